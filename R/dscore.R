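#' Threshold set for allelic XCI classification
#'
#' Bundles the three cutoffs of the allele-specific analysis: the minimum
#' number of allelically assigned reads for a feature to be analyzable, the
#' Xi/Xa read ratio at or above which a gene is called an XCI escape gene in
#' wild type, and the d-score shift at or above which a feature is called
#' Xist-dependent (or, symmetrically, increased/decreased for peaks).
#'
#' All boundaries are inclusive: a gene with exactly `reads_xi / reads_xa ==
#' escape_ratio` escapes, and a feature with a d-score shift of exactly
#' `delta_d` is dependent/increased.
#'
#' @param min_allelic_reads minimum `reads_xi + reads_xa` for analyzability
#'   (default 10).
#' @param escape_ratio Xi/Xa ratio cutoff for escape (default 0.05). Applied by
#'   integer cross-multiplication, so `xa == 0` with `xi > 0` is escape.
#' @param delta_d d-score difference cutoff (default 0.03).
#' @return An object of class `xci_thresholds`.
#' @examples
#' xci_thresholds()
#' xci_thresholds(min_allelic_reads = 20)
#' @export
xci_thresholds <- function(min_allelic_reads = 10L, escape_ratio = 0.05,
                           delta_d = 0.03) {
  .stop_if(!is.numeric(min_allelic_reads) || length(min_allelic_reads) != 1L ||
             min_allelic_reads <= 0 || min_allelic_reads != round(min_allelic_reads),
           "'min_allelic_reads' must be a single positive integer")
  .stop_if(!is.numeric(escape_ratio) || length(escape_ratio) != 1L ||
             escape_ratio <= 0, "'escape_ratio' must be a single positive number")
  .stop_if(!is.numeric(delta_d) || length(delta_d) != 1L || delta_d <= 0,
           "'delta_d' must be a single positive number")
  structure(list(min_allelic_reads = as.integer(min_allelic_reads),
                 escape_ratio = escape_ratio,
                 delta_d = delta_d),
            class = "xci_thresholds")
}

#' @export
print.xci_thresholds <- function(x, ...) {
  cat("XCI classification thresholds:\n",
      "  analyzable if reads_xi + reads_xa >= ", x$min_allelic_reads, "\n",
      "  escape if reads_xi / reads_xa >= ", x$escape_ratio, " (in WT)\n",
      "  dependent/increased if d-score shift >= ", x$delta_d, "\n", sep = "")
  invisible(x)
}

.check_allelic <- function(counts) {
  .stop_if(!is.data.frame(counts), "allelic counts must be a data.frame")
  need <- c("feature_id", "reads_xi", "reads_xa")
  miss <- setdiff(need, names(counts))
  .stop_if(length(miss) > 0L,
           "allelic count table lacks column(s): ", paste(miss, collapse = ", "))
  xi <- counts$reads_xi; xa <- counts$reads_xa
  .stop_if(any(!is.finite(xi)) || any(!is.finite(xa)),
           "allelic read counts must be finite")
  .stop_if(any(xi < 0) || any(xa < 0), "allelic read counts must be >= 0")
  .stop_if(any(xi != round(xi)) || any(xa != round(xa)),
           "allelic read counts must be integers")
  .stop_if(anyDuplicated(counts$feature_id) > 0L,
           "duplicated feature_id in allelic count table")
  invisible(counts)
}

#' Compute allelic d-scores
#'
#' The d-score of a feature is `reads_xi / (reads_xi + reads_xa) - 0.5`:
#' -0.5 means fully Xa-monoallelic (complete silencing of the Xi copy), 0
#' means biallelic balance. A feature is allelically analyzable when it has at
#' least `th$min_allelic_reads` allelically assigned reads; the d-score is
#' `NA` otherwise.
#'
#' @param counts data.frame with columns `feature_id`, `reads_xi`, `reads_xa`
#'   (non-negative integer read counts assigned to the inactive and active X
#'   allele), optionally `condition`.
#' @param th an [xci_thresholds()] object.
#' @return data.frame with columns `feature_id`, `reads_xi`, `reads_xa`,
#'   `d_score` (`NA` when not analyzable) and `analyzable`.
#' @examples
#' compute_dscore(data.frame(feature_id = c("g1", "g2"),
#'                           reads_xi = c(10L, 4L), reads_xa = c(10L, 4L)))
#' @export
compute_dscore <- function(counts, th = xci_thresholds()) {
  .check_allelic(counts)
  total <- counts$reads_xi + counts$reads_xa
  analyzable <- total >= th$min_allelic_reads
  d <- ifelse(analyzable, counts$reads_xi / total - 0.5, NA_real_)
  data.frame(feature_id = counts$feature_id,
             reads_xi = counts$reads_xi,
             reads_xa = counts$reads_xa,
             d_score = d,
             analyzable = analyzable,
             stringsAsFactors = FALSE)
}

#' Classify XCI escape versus subjective genes
#'
#' A gene escapes XCI when its wild-type Xi read count is at least
#' `escape_ratio` times its Xa read count (`reads_xi / reads_xa >= 0.05` by
#' default, boundary inclusive). The comparison is done by integer
#' cross-multiplication (`reads_xi * den >= num * reads_xa` with `num/den`
#' the exact fraction of the ratio), so it is exact at the boundary and a gene
#' with `reads_xa == 0` and `reads_xi > 0` escapes.
#'
#' Every input row must be analyzable under `th`; callers are expected to
#' filter first (an error is raised otherwise).
#'
#' @param wt wild-type allelic count data.frame (see [compute_dscore()]).
#' @inheritParams compute_dscore
#' @return character vector, `"escape"` or `"subjective"`, one per row.
#' @examples
#' classify_escape(data.frame(feature_id = c("a", "b"),
#'                            reads_xi = c(5L, 4L), reads_xa = c(100L, 100L)))
#' @export
classify_escape <- function(wt, th = xci_thresholds()) {
  .check_allelic(wt)
  total <- wt$reads_xi + wt$reads_xa
  .stop_if(any(total < th$min_allelic_reads),
           "classify_escape() requires allelically analyzable input; ",
           "filter with compute_dscore() first")
  fr <- .as_fraction(th$escape_ratio)
  ifelse(wt$reads_xi * fr$den >= fr$num * wt$reads_xa, "escape", "subjective")
}

.check_record_pair <- function(d1, d2) {
  .stop_if(!is.data.frame(d1) || !is.data.frame(d2) ||
             !all(c("feature_id", "d_score", "analyzable") %in% names(d1)) ||
             !all(c("feature_id", "d_score", "analyzable") %in% names(d2)),
           "inputs must be d-score records from compute_dscore()")
  .stop_if(nrow(d1) != nrow(d2) || any(d1$feature_id != d2$feature_id),
           "d-score records have mismatched feature ids")
  .stop_if(any(!d1$analyzable) || any(!d2$analyzable),
           "both d-score records must be analyzable; filter first")
}

#' Classify Xist-dependent versus independent features
#'
#' A feature is Xist-dependent when its d-score in the mutant condition
#' exceeds the reference condition by at least `th$delta_d` (default 0.03,
#' inclusive); otherwise it is Xist-independent.
#'
#' @param d1 reference-condition d-score records (e.g. WT), from
#'   [compute_dscore()]; all rows must be analyzable.
#' @param d2 perturbed-condition d-score records (e.g. after Xist deletion),
#'   matched row-by-row to `d1`.
#' @inheritParams compute_dscore
#' @return data.frame with `feature_id`, `delta_d` (d2 - d1) and `dependence`
#'   (`"dependent"` or `"independent"`).
#' @export
classify_dependence <- function(d1, d2, th = xci_thresholds()) {
  .check_record_pair(d1, d2)
  delta <- d2$d_score - d1$d_score
  data.frame(feature_id = d1$feature_id,
             delta_d = delta,
             dependence = ifelse(delta >= th$delta_d - .XCI_EPS,
                                 "dependent", "independent"),
             stringsAsFactors = FALSE)
}

#' Three-way d-score change classification
#'
#' Classifies each feature as `increased` (shift >= `delta_d`), `decreased`
#' (shift <= `-delta_d`) or `unchanged`, with inclusive boundaries. This is
#' the rule used for allelic ATAC/ChIP peaks and for the shYY1 versus shSCR
#' comparison.
#'
#' @inheritParams classify_dependence
#' @return data.frame with `feature_id`, `delta_d` and `change`.
#' @export
classify_dscore_change <- function(d1, d2, th = xci_thresholds()) {
  .check_record_pair(d1, d2)
  delta <- d2$d_score - d1$d_score
  change <- ifelse(delta >= th$delta_d - .XCI_EPS, "increased",
                   ifelse(delta <= -th$delta_d + .XCI_EPS, "decreased",
                          "unchanged"))
  data.frame(feature_id = d1$feature_id, delta_d = delta, change = change,
             stringsAsFactors = FALSE)
}

#' Run the allele-specific XCI classification pipeline
#'
#' End-to-end allelic arm: computes d-scores in both conditions, restricts to
#' features analyzable in both, classifies XCI escape status from the
#' wild-type counts only, and Xist dependence (and the three-way change class)
#' from the d-score difference.
#'
#' @param wt,mut allelic count data.frames (columns `feature_id`, `reads_xi`,
#'   `reads_xa`) for the reference and perturbed condition.
#' @inheritParams compute_dscore
#' @param exclude optional character vector of feature ids to drop before
#'   classification (e.g. `"Xist"`).
#' @return data.frame of class `xci_classification` with one row per feature
#'   analyzable in both conditions: `feature_id`, `reads_xi_wt`, `reads_xa_wt`,
#'   `d_wt`, `d_mut`, `delta_d`, `xci_status`, `dependence`, `change`, and
#'   `xa_zero_wt` (flag for the unbounded-ratio case `reads_xa == 0`). Summary
#'   counts are attached as the `"summary"` attribute.
#' @examples
#' sim <- simulate_allelic_counts(allelic_sim_config(n_genes = 50, seed = 1))
#' cls <- run_allelic_pipeline(sim$wt, sim$mut)
#' attr(cls, "summary")
#' @export
run_allelic_pipeline <- function(wt, mut, th = xci_thresholds(),
                                 exclude = NULL) {
  .check_allelic(wt); .check_allelic(mut)
  if (!is.null(exclude)) {
    wt <- wt[!wt$feature_id %in% exclude, , drop = FALSE]
    mut <- mut[!mut$feature_id %in% exclude, , drop = FALSE]
  }
  dw <- compute_dscore(wt, th)
  dm <- compute_dscore(mut, th)
  ids <- intersect(dw$feature_id[dw$analyzable], dm$feature_id[dm$analyzable])
  if (length(ids) == 0L) {
    warning("no feature is allelically analyzable in both conditions; ",
            "returning an empty classification", call. = FALSE)
    out <- data.frame(feature_id = character(0), reads_xi_wt = integer(0),
                      reads_xa_wt = integer(0), d_wt = numeric(0),
                      d_mut = numeric(0), delta_d = numeric(0),
                      xci_status = character(0), dependence = character(0),
                      change = character(0), xa_zero_wt = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("xci_classification", "data.frame")
    attr(out, "summary") <- c(n_analyzable = 0L)
    return(out)
  }
  dw <- dw[match(ids, dw$feature_id), ]
  dm <- dm[match(ids, dm$feature_id), ]
  esc <- classify_escape(dw[, c("feature_id", "reads_xi", "reads_xa")], th)
  dep <- classify_dependence(dw, dm, th)
  chg <- classify_dscore_change(dw, dm, th)
  out <- data.frame(feature_id = ids,
                    reads_xi_wt = dw$reads_xi,
                    reads_xa_wt = dw$reads_xa,
                    d_wt = dw$d_score,
                    d_mut = dm$d_score,
                    delta_d = dep$delta_d,
                    xci_status = esc,
                    dependence = dep$dependence,
                    change = chg$change,
                    xa_zero_wt = dw$reads_xa == 0L & dw$reads_xi > 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("xci_classification", "data.frame")
  attr(out, "summary") <- c(
    n_analyzable = length(ids),
    n_escape = sum(esc == "escape"),
    n_subjective = sum(esc == "subjective"),
    n_dependent = sum(out$dependence == "dependent"),
    n_dependent_escape = sum(out$dependence == "dependent" & esc == "escape"),
    n_dependent_subjective = sum(out$dependence == "dependent" &
                                   esc == "subjective"))
  out
}

#' @export
print.xci_classification <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Allele-specific XCI classification\n")
  cat("  features analyzable in both conditions:", s[["n_analyzable"]], "\n")
  if (s[["n_analyzable"]] > 0L) {
    cat("  XCI escape:", s[["n_escape"]],
        " subjective:", s[["n_subjective"]], "\n")
    cat("  Xist-dependent:", s[["n_dependent"]],
        " (escape:", s[["n_dependent_escape"]],
        ", subjective:", s[["n_dependent_subjective"]], ")\n")
  }
  if (nrow(x) > 0L) {
    cat("\n")
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  }
  invisible(x)
}
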