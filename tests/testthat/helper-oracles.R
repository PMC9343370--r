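# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths: exact integer arithmetic
# for the rational threshold rules, naive O(n^2) loops for interval ops,
# full enumeration for the exact tests.

# --- allelic rules, exact rational arithmetic via integers ------------------

oracle_dscore <- function(xi, xa, min_reads = 10L) {
  n <- xi + xa
  list(analyzable = n >= min_reads,
       d = ifelse(n >= min_reads, xi / n - 0.5, NA_real_))
}

# escape iff xi/xa >= 1/20, as integer cross-multiplication
oracle_escape <- function(xi, xa) xi * 20 >= xa

# (xi2/n2 - xi1/n1) >= 3/100, exact in integers (n1, n2 > 0)
oracle_dependent <- function(xi1, xa1, xi2, xa2) {
  n1 <- xi1 + xa1; n2 <- xi2 + xa2
  100 * (xi2 * n1 - xi1 * n2) >= 3 * n1 * n2
}

oracle_change <- function(xi1, xa1, xi2, xa2) {
  n1 <- xi1 + xa1; n2 <- xi2 + xa2
  lhs <- 100 * (xi2 * n1 - xi1 * n2)
  rhs <- 3 * n1 * n2
  ifelse(lhs >= rhs, "increased", ifelse(lhs <= -rhs, "decreased",
                                         "unchanged"))
}

# --- exact tests ------------------------------------------------------------

# two-sided Fisher by enumeration with exact integer hypergeometric
# numerators (all values < 2^53 for totals <= 40); same probability-mass tie
# rule as the implementation, applied to exact numerators
oracle_fisher <- function(a, b, c, d, tie_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, k) * choose(r2, c1 - k)
  obs <- choose(r1, a) * choose(r2, c)
  min(1, sum(num[num <= obs * (1 + tie_tol)]) / choose(N, c1))
}

oracle_ks_stat <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(v) - ecdf(y)(v)))
}

# permutation p-value by full enumeration over label assignments
oracle_ks_perm <- function(x, y) {
  pool <- c(x, y)
  dobs <- oracle_ks_stat(x, y)
  cmb <- combn(length(pool), length(x))
  ds <- apply(cmb, 2, function(i) oracle_ks_stat(pool[i], pool[-i]))
  mean(ds >= dobs - 1e-12)
}

# --- naive interval oracles (0-based half-open) -----------------------------

oracle_overlap1 <- function(c1, s1, e1, c2, s2, e2)
  c1 == c2 && min(e1, e2) - max(s1, s2) >= 1

oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i)
    any(vapply(seq_len(nrow(subject)), function(j)
      oracle_overlap1(query$chrom[i], query$start[i], query$end[i],
                      subject$chrom[j], subject$start[j], subject$end[j]),
      logical(1))), logical(1))
}

# transitive merge by sort-and-sweep, independent of IRanges
oracle_merge <- function(x, max_gap) {
  out <- NULL
  for (ch in sort(unique(x$chrom))) {
    sub <- x[x$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cs <- sub$start[1]; ce <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - ce <= max_gap) ce <- max(ce, sub$end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
             cs <- sub$start[i]; ce <- sub$end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
  }
  out
}

oracle_tss <- function(genes)
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)

oracle_partition <- function(peaks, genes, window = 3000) {
  tss <- oracle_tss(genes)
  win <- data.frame(chrom = genes$chrom, start = pmax(0L, tss - window),
                    end = tss + window + 1L)
  ifelse(oracle_overlaps_any(peaks, win), "proximal", "distal")
}

oracle_yy1_class <- function(yy1, h3k27ac, genes, w_prom = 3000,
                             w_enh = 125000) {
  tss <- oracle_tss(genes)
  prom <- data.frame(chrom = genes$chrom, start = pmax(0L, tss - w_prom),
                     end = tss + w_prom + 1L)
  band <- data.frame(chrom = genes$chrom, start = pmax(0L, tss - w_enh),
                     end = tss + w_enh + 1L)
  is_p <- oracle_overlaps_any(yy1, prom)
  has_ac <- if (nrow(h3k27ac) > 0) oracle_overlaps_any(yy1, h3k27ac)
            else rep(FALSE, nrow(yy1))
  in_b <- oracle_overlaps_any(yy1, band)
  ifelse(is_p, "promoter",
         ifelse(has_ac & in_b, "enhancer", "other"))
}

# --- fixture builders -------------------------------------------------------

random_intervals <- function(n, n_chrom = 2, max_pos = 10000,
                             max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

allelic_df <- function(xi, xa, ids = NULL) {
  data.frame(feature_id = ids %||% sprintf("g%d", seq_along(xi)),
             reads_xi = as.integer(xi), reads_xa = as.integer(xa),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
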