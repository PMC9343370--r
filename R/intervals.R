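# Interval conventions: 0-based half-open [start, end) throughout (BED).
# Overlap means >= 1 shared bp; abutting intervals do not overlap.
# Distance between disjoint intervals is the half-open gap (abutting = 0).

.check_intervals <- function(x, what = "interval table") {
  .stop_if(!is.data.frame(x), what, " must be a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  .stop_if(length(miss) > 0L, what, " lacks column(s): ",
           paste(miss, collapse = ", "))
  .stop_if(any(!is.finite(x$start)) || any(!is.finite(x$end)),
           what, ": coordinates must be finite")
  .stop_if(any(x$start < 0), what, ": start must be >= 0")
  .stop_if(any(x$start >= x$end), what, ": need start < end (half-open)")
  invisible(x)
}

# 0-based half-open -> GRanges (1-based closed)
.iv2gr <- function(x) {
  GRanges(seqnames = as.character(x$chrom),
          ranges = IRanges(start = x$start + 1L, end = x$end))
}

.gr2iv <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' ATAC/ChIP signal density within a region (RPKM)
#'
#' `RPKM = 1e6 * reads in region / (total reads * region width in kb)`.
#'
#' @param read_count reads counted within the region(s).
#' @param total_reads total mapped reads in the sample (> 0).
#' @param region_width_bp region width(s) in bp (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(100, 1e6, 2000) # 50
#' @export
rpkm <- function(read_count, total_reads, region_width_bp) {
  .stop_if(any(total_reads <= 0), "'total_reads' must be > 0")
  .stop_if(any(region_width_bp <= 0), "'region_width_bp' must be > 0")
  .stop_if(any(read_count < 0), "'read_count' must be >= 0")
  1e6 * read_count / (total_reads * region_width_bp / 1000)
}

#' Normalized peak intensity (RPK)
#'
#' `RPK = normalized reads in peak / peak width in kb`.
#'
#' @param normalized_count size-factor-normalized read count(s) in the peak.
#' @param peak_width_bp peak width(s) in bp (> 0).
#' @return numeric RPK value(s).
#' @examples
#' rpk(500, 2500) # 200
#' @export
rpk <- function(normalized_count, peak_width_bp) {
  .stop_if(any(peak_width_bp <= 0), "'peak_width_bp' must be > 0")
  .stop_if(any(normalized_count < 0), "'normalized_count' must be >= 0")
  normalized_count / (peak_width_bp / 1000)
}

#' Overlap of each query interval with any subject interval
#'
#' Two intervals overlap when they are on the same chromosome and share at
#' least 1 bp in half-open arithmetic (abutting intervals do not overlap).
#'
#' @param query,subject interval data.frames with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return logical vector, one per `query` row.
#' @examples
#' a <- data.frame(chrom = "c", start = 100, end = 200)
#' b <- data.frame(chrom = "c", start = c(199, 200), end = c(300, 300))
#' interval_overlaps(b, a) # TRUE, FALSE
#' @export
interval_overlaps <- function(query, subject) {
  .check_intervals(query, "'query'"); .check_intervals(subject, "'subject'")
  # seqlevel-mismatch warnings are expected when query and subject touch
  # disjoint chromosome sets; overlap is simply absent there
  hits <- suppressWarnings(
    findOverlaps(.iv2gr(query), .iv2gr(subject), minoverlap = 1L))
  seq_len(nrow(query)) %in% queryHits(hits)
}

#' Merge nearby intervals
#'
#' Intervals on the same chromosome whose half-open gap is at most `max_gap`
#' bp are unioned transitively (the bedtools `merge -d` convention; `max_gap
#' = 0` merges only overlapping or abutting intervals). Output is sorted and
#' pairwise separated by more than `max_gap`.
#'
#' @param x interval data.frame (`chrom`, `start`, `end`).
#' @param max_gap maximum gap to bridge, in bp (default 1000).
#' @return merged interval data.frame.
#' @examples
#' merge_peaks(data.frame(chrom = "c", start = c(100, 1150),
#'                        end = c(200, 1300)), max_gap = 1000)
#' @export
merge_peaks <- function(x, max_gap = 1000) {
  .check_intervals(x)
  .stop_if(max_gap < 0, "'max_gap' must be >= 0")
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  gr <- reduce(.iv2gr(x), min.gapwidth = max_gap + 1L)
  out <- .gr2iv(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus peaks across samples
#'
#' Candidate regions are formed by unioning all samples' peaks (overlapping
#' or abutting intervals are chained); a region is retained when the fraction
#' of samples contributing at least one overlapping (>= 1 bp) peak is at
#' least `min_fraction` (inclusive: 2 of 4 samples pass at 0.5).
#'
#' @param peak_sets list of per-sample interval data.frames.
#' @param min_fraction minimum supporting fraction of samples (default 0.5).
#' @return interval data.frame of retained consensus regions with a
#'   `n_samples` support column.
#' @export
consensus_peaks <- function(peak_sets, min_fraction = 0.5) {
  .stop_if(!is.list(peak_sets) || length(peak_sets) == 0L,
           "'peak_sets' must be a non-empty list of interval tables")
  for (p in peak_sets) .check_intervals(p)
  all_pk <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(all_pk) == 0L) return(empty)
  regions <- .gr2iv(reduce(.iv2gr(all_pk)))
  support <- rep(0L, nrow(regions))
  for (p in peak_sets)
    support <- support + (if (nrow(p) > 0L)
      as.integer(interval_overlaps(regions, p)) else 0L)
  keep <- support / length(peak_sets) >= min_fraction - .XCI_EPS
  out <- regions[keep, , drop = FALSE]
  out$n_samples <- support[keep]
  rownames(out) <- NULL
  out
}

.check_genes <- function(genes) {
  .check_intervals(genes, "gene model table")
  .stop_if(!all(c("gene_id", "strand") %in% names(genes)),
           "gene model table needs gene_id and strand columns")
  .stop_if(!all(genes$strand %in% c("+", "-")),
           "unstranded gene models are not supported; strand must be + or -")
  invisible(genes)
}

#' Transcription start sites of gene models
#'
#' TSS is the `start` coordinate for `+`-strand genes and `end - 1` for
#' `-`-strand genes (0-based). Unstranded genes are rejected.
#'
#' @param genes gene model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return integer vector of TSS positions, named by gene id.
#' @export
gene_tss <- function(genes) {
  .check_genes(genes)
  setNames(ifelse(genes$strand == "+", genes$start, genes$end - 1L),
           genes$gene_id)
}

# half-open window covering positions tss-w .. tss+w inclusive
.tss_windows <- function(genes, window) {
  tss <- gene_tss(genes)
  data.frame(chrom = genes$chrom,
             start = pmax(0L, tss - window),
             end = tss + window + 1L,
             gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' TSS-proximal versus TSS-distal partition of peaks
#'
#' A peak is TSS-proximal when it overlaps (>= 1 bp) the `±window` bp window
#' around any gene's TSS; otherwise it is TSS-distal. Every peak receives
#' exactly one label.
#'
#' @param peaks interval data.frame.
#' @inheritParams gene_tss
#' @param window half-width of the proximal window in bp (default 3000).
#' @return character vector, `"proximal"` or `"distal"`, one per peak.
#' @export
partition_tss <- function(peaks, genes, window = 3000) {
  .check_intervals(peaks, "'peaks'")
  if (nrow(peaks) == 0L) return(character(0))
  win <- .tss_windows(genes, window)
  ifelse(interval_overlaps(peaks, win), "proximal", "distal")
}

# half-open gap between [s1,e1) and [s2,e2) on one chrom; 0 if they overlap
# or abut
.gap_bp <- function(s1, e1, s2, e2) pmax(0L, pmax(s1, s2) - pmin(e1, e2))

#' Annotate peaks to genes
#'
#' TSS-proximal peaks (per [partition_tss()]) are annotated to the gene with
#' the closest TSS, measured from the peak midpoint; TSS-distal peaks are
#' annotated to the gene with the closest gene body (distance 0 when they
#' overlap). Equidistant ties go to the lexicographically smallest gene id
#' and are flagged ambiguous. Peaks on a chromosome with no genes are left
#' unassigned and flagged.
#'
#' @inheritParams partition_tss
#' @return data.frame with one row per peak: `chrom`, `start`, `end`,
#'   `tss_class`, `gene_id` (`NA` if unassigned), `distance` and `ambiguous`.
#' @export
annotate_peaks <- function(peaks, genes, window = 3000) {
  .check_intervals(peaks, "'peaks'"); .check_genes(genes)
  cls <- partition_tss(peaks, genes, window)
  tss <- gene_tss(genes)
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  amb <- rep(FALSE, n)
  mid <- floor((peaks$start + peaks$end) / 2)
  for (i in seq_len(n)) {
    on_chr <- which(genes$chrom == peaks$chrom[i])
    if (length(on_chr) == 0L) next
    d <- if (cls[i] == "proximal") {
      abs(mid[i] - tss[on_chr])
    } else {
      .gap_bp(peaks$start[i], peaks$end[i],
              genes$start[on_chr], genes$end[on_chr])
    }
    best <- on_chr[d == min(d)]
    cand <- sort(genes$gene_id[best])
    gene_id[i] <- cand[1L]
    dist[i] <- min(d)
    amb[i] <- length(cand) > 1L
  }
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             tss_class = cls, gene_id = gene_id, distance = dist,
             ambiguous = amb, stringsAsFactors = FALSE)
}

#' Replicate-consistent peak intensity change
#'
#' The peak analogue of [call_deg()]: a peak is increased (decreased) when
#' its intensity (e.g. RPK) is higher (lower) in the perturbed condition in
#' every replicate comparison; anything else — including ties — is
#' unchanged.
#'
#' @param wt,ko peak x replicate matrices of intensities, replicates paired
#'   by column index (or all pairs with `pairing = "allpairs"`).
#' @inheritParams call_deg
#' @return character vector `increased`/`decreased`/`unchanged`, one per
#'   peak.
#' @examples
#' classify_replicate_change(cbind(c(10, 10), c(12, 12)),
#'                           cbind(c(20, 20), c(22, 8)))
#' @export
classify_replicate_change <- function(wt, ko, pairing = c("index", "allpairs")) {
  pairing <- match.arg(pairing)
  wt <- as.matrix(wt); ko <- as.matrix(ko)
  .stop_if(nrow(wt) != nrow(ko), "WT and KO must cover the same peaks")
  if (pairing == "index") {
    .stop_if(ncol(wt) != ncol(ko),
             "index pairing needs equal replicate numbers")
    up <- rowSums(ko > wt) == ncol(wt)
    down <- rowSums(ko < wt) == ncol(wt)
  } else {
    up <- rep(TRUE, nrow(wt)); down <- rep(TRUE, nrow(wt))
    for (i in seq_len(ncol(ko))) for (j in seq_len(ncol(wt))) {
      up <- up & (ko[, i] > wt[, j])
      down <- down & (ko[, i] < wt[, j])
    }
  }
  ifelse(up, "increased", ifelse(down, "decreased", "unchanged"))
}

#' Promoter and enhancer classification of YY1 peaks
#'
#' A YY1 peak is a promoter peak when it lies within ±`promoter_window` bp of
#' any TSS (overlap of the peak interval with the window, as in
#' [partition_tss()]). Otherwise it is an enhancer peak when it overlaps
#' (>= 1 bp) at least one H3K27ac peak and lies within `promoter_window` to
#' `enhancer_max` bp of some TSS. Anything else is `other`. Promoter peaks
#' are annotated to all genes with a TSS within ±`promoter_window`; enhancer
#' peaks to all genes with a TSS within ±`enhancer_max` — one peak may
#' annotate many genes. Promoter and enhancer labels are disjoint because
#' promoters are assigned first.
#'
#' @param yy1 YY1 peak interval data.frame.
#' @param h3k27ac H3K27ac peak interval data.frame.
#' @inheritParams gene_tss
#' @param promoter_window promoter half-window in bp (default 3000).
#' @param enhancer_max outer bound of the enhancer band in bp (default
#'   125000).
#' @return list of class `yy1_classification`: `class` (character per peak)
#'   and `annotations` (data.frame `peak`, `gene_id`, `class`; one row per
#'   peak-gene link).
#' @export
classify_yy1_peaks <- function(yy1, h3k27ac, genes, promoter_window = 3000,
                               enhancer_max = 125000) {
  .check_intervals(yy1, "'yy1'"); .check_intervals(h3k27ac, "'h3k27ac'")
  .check_genes(genes)
  n <- nrow(yy1)
  if (n == 0L)
    return(structure(list(class = character(0),
                          annotations = data.frame(peak = integer(0),
                                                   gene_id = character(0),
                                                   class = character(0))),
                     class = "yy1_classification"))
  win_prom <- .tss_windows(genes, promoter_window)
  win_enh <- .tss_windows(genes, enhancer_max)
  is_prom <- interval_overlaps(yy1, win_prom)
  has_ac <- if (nrow(h3k27ac) > 0L) interval_overlaps(yy1, h3k27ac)
            else rep(FALSE, n)
  in_band <- interval_overlaps(yy1, win_enh)
  is_enh <- !is_prom & has_ac & in_band
  cls <- ifelse(is_prom, "promoter", ifelse(is_enh, "enhancer", "other"))
  ann_one <- function(idx, win, label) {
    if (length(idx) == 0L) return(NULL)
    hits <- suppressWarnings(
      findOverlaps(.iv2gr(yy1[idx, , drop = FALSE]), .iv2gr(win),
                   minoverlap = 1L))
    if (length(hits) == 0L) return(NULL)
    data.frame(peak = idx[queryHits(hits)],
               gene_id = win$gene_id[subjectHits(hits)],
               class = label, stringsAsFactors = FALSE)
  }
  ann <- rbind(ann_one(which(is_prom), win_prom, "promoter"),
               ann_one(which(is_enh), win_enh, "enhancer"))
  if (is.null(ann))
    ann <- data.frame(peak = integer(0), gene_id = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  ann <- unique(ann[order(ann$peak, ann$gene_id), , drop = FALSE])
  rownames(ann) <- NULL
  structure(list(class = cls, annotations = ann),
            class = "yy1_classification")
}

#' @export
print.yy1_classification <- function(x, ...) {
  cat("YY1 peak classification:\n")
  print(table(x$class))
  cat(nrow(x$annotations), "peak-gene annotations\n")
  invisible(x)
}
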