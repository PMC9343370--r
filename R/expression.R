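#' FPKM from a raw count matrix
#'
#' `FPKM = 1e9 * count / (total counts in sample * gene length in bp)` —
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts gene x sample matrix of non-negative raw counts, with row
#'   names as gene ids.
#' @param lengths positive gene lengths in bp, one per row of `counts`.
#' @return matrix of FPKM values, same dimensions as `counts`.
#' @examples
#' compute_fpkm(matrix(1000, 1, 1, dimnames = list("g", "s")), lengths = 2000)
#' @export
compute_fpkm <- function(counts, lengths) {
  counts <- .check_counts(counts)
  .stop_if(length(lengths) != nrow(counts),
           "'lengths' must have one entry per gene")
  .stop_if(any(!is.finite(lengths)) || any(lengths <= 0),
           "gene lengths must be positive")
  totals <- colSums(counts)
  .stop_if(any(totals == 0), "every sample must have total count > 0")
  1e9 * sweep(counts, 2, totals, "/") / lengths
}

#' Median-of-ratios size factors
#'
#' The median-of-ratios normalizer: a pseudo-reference sample is formed as the
#' per-gene geometric mean over samples (using only genes with a positive
#' count in every sample), and each sample's size factor is the median of its
#' count ratios to that reference.
#'
#' @inheritParams compute_fpkm
#' @return positive numeric vector of size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' size_factors_median_of_ratios(m)
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- .check_counts(counts)
  .stop_if(ncol(counts) < 2L, "need at least two samples")
  ref_ok <- rowSums(counts > 0) == ncol(counts)
  .stop_if(!any(ref_ok),
           "normalization error: no gene has a positive count in every sample")
  lc <- log(counts[ref_ok, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - ref)))
  setNames(sf, colnames(counts))
}

#' Flag actively transcribed genes
#'
#' A gene is active when its mean FPKM is at or above `threshold` (default 1,
#' inclusive) in at least one genotype (`scope = "any"`), in both genotypes
#' (`"both"`), or in the reference genotype (`"wt"`).
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param genotype character/factor of length `ncol(fpkm)` giving each
#'   sample's genotype; the first level (or `"WT"` if present) is treated as
#'   the reference for `scope = "wt"`.
#' @param threshold FPKM cutoff (default 1).
#' @param scope where the cutoff must hold; default `"any"`.
#' @return logical vector, one per gene.
#' @export
call_active <- function(fpkm, genotype, threshold = 1,
                        scope = c("any", "both", "wt")) {
  scope <- match.arg(scope)
  .stop_if(length(genotype) != ncol(fpkm),
           "'genotype' must label every sample")
  genotype <- as.character(genotype)
  lev <- unique(genotype)
  means <- vapply(lev, function(g)
    rowMeans(fpkm[, genotype == g, drop = FALSE]), numeric(nrow(fpkm)))
  if (nrow(fpkm) == 1L) means <- matrix(means, nrow = 1L)
  ok <- means >= threshold
  switch(scope,
         any = rowSums(ok) >= 1L,
         both = rowSums(ok) == length(lev),
         wt = {
           ref <- if ("WT" %in% lev) "WT" else lev[1L]
           ok[, ref]
         })
}

#' Replicate-consistent differential expression calls
#'
#' An active gene is called up (down) when its normalized count is higher
#' (lower) in the perturbed condition than in the reference in every replicate
#' comparison. Replicates are compared by index (WT rep i vs KO rep i) by
#' default, or by all pairs. Ties are neither an increase nor a decrease, so
#' any tied comparison yields `"non"`.
#'
#' @param norm_counts gene x sample matrix of size-factor-normalized counts.
#' @param wt_cols,ko_cols column indices or names of the reference and
#'   perturbed samples; equal length when `pairing = "index"`.
#' @param active logical per-gene activity flags (from [call_active()]);
#'   inactive genes are always `"non"`. Default: all active.
#' @param pairing `"index"` (default) or `"allpairs"`.
#' @return data.frame with `gene_id`, `direction` (`up`/`down`/`non`) and
#'   `active`.
#' @examples
#' m <- cbind(wt1 = c(100, 100), wt2 = c(110, 110),
#'            ko1 = c(150, 150), ko2 = c(160, 90))
#' rownames(m) <- c("g1", "g2")
#' call_deg(m, wt_cols = 1:2, ko_cols = 3:4)
#' @export
call_deg <- function(norm_counts, wt_cols, ko_cols, active = NULL,
                     pairing = c("index", "allpairs")) {
  pairing <- match.arg(pairing)
  w <- norm_counts[, wt_cols, drop = FALSE]
  k <- norm_counts[, ko_cols, drop = FALSE]
  if (pairing == "index") {
    .stop_if(ncol(w) != ncol(k),
             "index pairing needs equal numbers of WT and KO replicates")
    up <- rowSums(k > w) == ncol(w)
    down <- rowSums(k < w) == ncol(w)
  } else {
    up <- rep(TRUE, nrow(w)); down <- rep(TRUE, nrow(w))
    for (i in seq_len(ncol(k))) for (j in seq_len(ncol(w))) {
      up <- up & (k[, i] > w[, j])
      down <- down & (k[, i] < w[, j])
    }
  }
  if (is.null(active)) active <- rep(TRUE, nrow(norm_counts))
  .stop_if(length(active) != nrow(norm_counts),
           "'active' must have one flag per gene")
  direction <- ifelse(active & up, "up", ifelse(active & down, "down", "non"))
  data.frame(gene_id = rownames(norm_counts), direction = direction,
             active = active, row.names = NULL, stringsAsFactors = FALSE)
}

#' Scope DEGs into common and lineage-specific sets
#'
#' A gene is a common DEG (cDEG) when it is a DEG with the same direction in
#' every population; any other gene that is a DEG in at least one population
#' is a lineage-specific DEG (lsDEG). Also tallies the per-direction Venn
#' counts over populations.
#'
#' @param calls named list of per-population DEG call data.frames from
#'   [call_deg()], all over the same gene universe in the same order.
#' @return list of class `deg_scope`: `scope` (data.frame `gene_id`, `scope`,
#'   `direction` — the shared direction for cDEGs, `NA` otherwise — and
#'   `populations`, a comma-separated list of populations where the gene is a
#'   DEG) and `venn` (per-direction tables of population-combination counts).
#' @export
scope_degs <- function(calls) {
  .stop_if(!is.list(calls) || length(calls) < 2L,
           "'calls' must be a named list of at least two populations")
  pops <- names(calls)
  .stop_if(is.null(pops) || any(pops == ""), "'calls' must be fully named")
  ids <- calls[[1L]]$gene_id
  for (p in pops)
    .stop_if(!identical(calls[[p]]$gene_id, ids),
             "all populations must share one gene universe (same order)")
  dirs <- vapply(calls, function(d) d$direction, character(length(ids)))
  if (length(ids) == 1L) dirs <- matrix(dirs, nrow = 1L)
  is_deg <- dirs != "non"
  any_deg <- rowSums(is_deg) > 0L
  all_same <- rowSums(is_deg) == length(pops) &
    apply(dirs, 1L, function(x) length(unique(x)) == 1L)
  scope <- ifelse(all_same, "cDEG", ifelse(any_deg, "lsDEG", NA_character_))
  keep <- which(any_deg)
  venn <- lapply(c(up = "up", down = "down"), function(dd) {
    combo <- apply(dirs == dd, 1L, function(r)
      paste(pops[r], collapse = "&"))
    table(combo[combo != ""])
  })
  structure(list(
    scope = data.frame(
      gene_id = ids[keep],
      scope = scope[keep],
      direction = ifelse(all_same[keep], dirs[keep, 1L], NA_character_),
      populations = apply(is_deg[keep, , drop = FALSE], 1L, function(r)
        paste(pops[r], collapse = ",")),
      row.names = NULL, stringsAsFactors = FALSE),
    venn = venn), class = "deg_scope")
}

#' @export
print.deg_scope <- function(x, ...) {
  n_c <- sum(x$scope$scope == "cDEG"); n_l <- sum(x$scope$scope == "lsDEG")
  cat("DEG scoping:", n_c, "cDEGs,", n_l, "lsDEGs\n")
  invisible(x)
}

#' Per-population signature genes
#'
#' A gene belongs to population P's signature when it is significantly
#' upregulated there (p < `alpha` and mean FPKM >= `fpkm_min`) and not
#' actively transcribed (mean FPKM < `fpkm_min`) in both other populations.
#' Signature sets are pairwise disjoint by construction. Exactly three
#' populations are required.
#'
#' @param fpkm_means gene x 3 matrix of per-population mean FPKM, with column
#'   names naming the populations.
#' @param pvalues gene x 3 matrix of per-population upregulation p-values
#'   (e.g. from [signature_pvalues()]), aligned with `fpkm_means`.
#' @param alpha significance cutoff (default 0.05, strict `<`).
#' @param fpkm_min activity cutoff (default 1; `>=` in the focal population,
#'   `<` in the others).
#' @return named list of three character vectors of gene ids.
#' @export
signature_genes <- function(fpkm_means, pvalues, alpha = 0.05, fpkm_min = 1) {
  .stop_if(ncol(fpkm_means) != 3L || ncol(pvalues) != 3L,
           "signature genes are defined for exactly three populations")
  .stop_if(!identical(dim(fpkm_means), dim(pvalues)),
           "'fpkm_means' and 'pvalues' must be aligned")
  ids <- rownames(fpkm_means)
  out <- lapply(1:3, function(j) {
    others <- setdiff(1:3, j)
    sel <- pvalues[, j] < alpha & fpkm_means[, j] >= fpkm_min &
      fpkm_means[, others[1L]] < fpkm_min & fpkm_means[, others[2L]] < fpkm_min
    ids[sel]
  })
  setNames(out, colnames(fpkm_means))
}

#' Welch-test p-values for signature-gene selection
#'
#' For each gene and each population, Welch's two-sample t-test of
#' `log2(FPKM + 1)` in the focal population's replicates against the pooled
#' replicates of the other populations, one-sided for upregulation. A helper
#' for [signature_genes()] when no externally computed p-values are supplied.
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param population character vector assigning each sample to a population.
#' @return gene x population matrix of p-values.
#' @export
signature_pvalues <- function(fpkm, population) {
  .stop_if(length(population) != ncol(fpkm),
           "'population' must label every sample")
  lf <- log2(fpkm + 1)
  pops <- unique(population)
  p <- matrix(NA_real_, nrow(fpkm), length(pops),
              dimnames = list(rownames(fpkm), pops))
  for (pp in pops) {
    foc <- population == pp
    for (g in seq_len(nrow(lf))) {
      x <- lf[g, foc]; y <- lf[g, !foc]
      p[g, pp] <- if (stats::var(x) + stats::var(y) == 0) 1 else
        t.test(x, y, alternative = "greater")$p.value
    }
  }
  p
}

#' Keyword-based functional grouping of genes
#'
#' Flags each gene for each category when at least one of its annotation term
#' names contains (case-insensitive substring) one of the category's keywords.
#'
#' @param annotations data.frame with columns `gene_id` and `term` (one row
#'   per gene-term link; supplied by the caller, no ontology is downloaded).
#' @param keywords named list of non-empty character keyword vectors, e.g.
#'   [xci_keyword_sets()].
#' @return data.frame with `gene_id` and one logical column per category.
#' @examples
#' ann <- data.frame(gene_id = "g1", term = "mitotic cell cycle")
#' keyword_group(ann, xci_keyword_sets())
#' @export
keyword_group <- function(annotations, keywords) {
  .stop_if(!is.data.frame(annotations) ||
             !all(c("gene_id", "term") %in% names(annotations)),
           "'annotations' must have columns gene_id and term")
  .stop_if(!is.list(keywords) || length(keywords) == 0L ||
             is.null(names(keywords)) ||
             any(vapply(keywords, length, 1L) == 0L),
           "'keywords' must be a non-empty named list of keyword vectors")
  ids <- unique(annotations$gene_id)
  terms <- tolower(annotations$term)
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (cat_name in names(keywords)) {
    hit <- rep(FALSE, length(terms))
    for (kw in tolower(keywords[[cat_name]]))
      hit <- hit | grepl(kw, terms, fixed = TRUE)
    out[[cat_name]] <- ids %in% annotations$gene_id[hit]
  }
  out
}

#' Canonical keyword sets for cell-cycle- and immune-related genes
#'
#' The term-name keyword lists used to group genes as cell-cycle-related or
#' immune-related when screening annotation tables.
#'
#' @return named list with elements `cell_cycle` and `immune`.
#' @export
xci_keyword_sets <- function() {
  list(cell_cycle = c("cell cycle", "nuclear division", "DNA replication",
                      "chromosome segregation", "chromatid segregation",
                      "chromatid separation"),
       immune = c("immune", "antigen", "interferon", "defense response"))
}

#' Fold-change vectors for the X-linked versus autosomal CDF comparison
#'
#' Computes per-gene expression fold changes (mean KO FPKM / mean WT FPKM)
#' over genes passing the activity filter, split into X-linked and autosomal
#' vectors ready for [ks_two_sample()].
#'
#' @param fpkm_wt,fpkm_ko gene x replicate FPKM matrices for the two
#'   genotypes, same genes in the same order.
#' @param chrom chromosome of each gene.
#' @param x_chrom chromosome name counted as X-linked (default `"chrX"`).
#' @param threshold activity cutoff applied as in [call_active()] with scope
#'   `"any"` (default 1).
#' @return list with numeric vectors `x` and `autosomal` (named by gene), and
#'   `n_dropped_zero_wt`, the number of filtered-in genes excluded because
#'   their WT mean was zero (warned about).
#' @export
foldchange_cdf <- function(fpkm_wt, fpkm_ko, chrom, x_chrom = "chrX",
                           threshold = 1) {
  fpkm_wt <- as.matrix(fpkm_wt); fpkm_ko <- as.matrix(fpkm_ko)
  .stop_if(nrow(fpkm_wt) != nrow(fpkm_ko) ||
             length(chrom) != nrow(fpkm_wt),
           "genotype matrices and 'chrom' must cover the same genes")
  mw <- rowMeans(fpkm_wt); mk <- rowMeans(fpkm_ko)
  keep <- mw >= threshold | mk >= threshold
  zero_wt <- keep & mw == 0
  if (any(zero_wt)) {
    warning(sum(zero_wt), " gene(s) with zero WT mean excluded from the ",
            "fold-change vectors", call. = FALSE)
    keep <- keep & !zero_wt
  }
  fc <- (mk / mw)[keep]
  ids <- rownames(fpkm_wt)
  if (!is.null(ids)) names(fc) <- ids[keep]
  is_x <- chrom[keep] == x_chrom
  list(x = fc[is_x], autosomal = fc[!is_x],
       n_dropped_zero_wt = sum(zero_wt))
}

.check_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  .stop_if(!is.matrix(counts) || !is.numeric(counts),
           "counts must be a numeric matrix")
  .stop_if(any(!is.finite(counts)) || any(counts < 0),
           "counts must be finite and >= 0")
  counts
}
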