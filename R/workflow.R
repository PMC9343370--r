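# The two end-to-end workflows: the allele-specific MEF arm and the
# non-allelic HSPC arm. Both accept in-memory objects or file paths, return
# classed result bundles, and can write their outputs plus a JSON manifest.

#' Run the allele-specific workflow
#'
#' d-scores in both conditions, escape/dependence classification restricted
#' to features analyzable in both, the escape-by-dependence association test,
#' and summary counts. Deterministic given its inputs.
#'
#' @param wt,mut allelic count data.frames or paths to allelic count TSVs.
#' @param th an [xci_thresholds()] object.
#' @param exclude optional feature ids to drop from the association (e.g.
#'   `"Xist"`); the classification table keeps them.
#' @param outdir optional directory; when given, the classification table,
#'   association summary and a JSON run manifest are written there.
#' @return list of class `xci_workflow`: `classification`
#'   (`xci_classification`), `association` (`xci_association`), `summary`
#'   (named counts) and `thresholds`.
#' @examples
#' sim <- simulate_allelic_counts(allelic_sim_config(seed = 11))
#' wf <- run_allelic_workflow(sim$wt, sim$mut)
#' wf$summary
#' @export
run_allelic_workflow <- function(wt, mut, th = xci_thresholds(),
                                 exclude = NULL, outdir = NULL) {
  if (is.character(wt)) wt <- read_allelic_tsv(wt)
  if (is.character(mut)) mut <- read_allelic_tsv(mut)
  cls <- run_allelic_pipeline(wt, mut, th)
  assoc <- if (nrow(cls) > 0L)
    escape_dependence_association(cls, exclude = exclude) else NULL
  res <- structure(list(classification = cls, association = assoc,
                        summary = attr(cls, "summary"), thresholds = th),
                   class = "xci_workflow")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f_cls <- file.path(outdir, "xci_classification.tsv")
    write.table(as.data.frame(cls), f_cls, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- f_cls
    if (!is.null(assoc)) {
      f_assoc <- file.path(outdir, "association.tsv")
      write.table(data.frame(cell = c("escape_dependent",
                                      "escape_independent",
                                      "subjective_dependent",
                                      "subjective_independent"),
                             count = as.vector(assoc$table),
                             p_value = assoc$test$p_value,
                             test = assoc$test$test_name),
                  f_assoc, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f_assoc)
    }
    .write_manifest(outdir, workflow = "allelic",
                    config = list(thresholds = unclass(th),
                                  exclude = exclude),
                    row_counts = list(
                      input_wt = nrow(wt), input_mut = nrow(mut),
                      analyzable_both = nrow(cls),
                      filtered_not_analyzable =
                        length(union(wt$feature_id, mut$feature_id)) -
                        nrow(cls) - length(exclude %||% character(0))),
                    files = files)
  }
  res
}

#' @export
print.xci_workflow <- function(x, ...) {
  print(x$classification)
  if (!is.null(x$association)) { cat("\n"); print(x$association) }
  invisible(x)
}

#' Run the non-allelic HSPC workflow
#'
#' Per population: median-of-ratios normalization over that population's
#' samples, FPKM, activity flags, replicate-consistent DEG calls; then
#' cDEG/lsDEG scoping across populations and the X-linked versus autosomal
#' fold-change K-S comparison per population. If peak inputs are supplied,
#' also: consensus peaks per condition, merged peak universe, TSS partition
#' and nearest-gene annotation, replicate-consistent intensity changes, and
#' promoter/enhancer YY1 classification.
#'
#' @param counts gene x sample count matrix (row names = gene ids) or a path
#'   to a counts TSV (then `lengths` is taken from the file).
#' @param lengths gene lengths in bp.
#' @param meta data.frame with columns `sample`, `population`, `genotype`
#'   (`WT`/`KO`), `replicate`, matching the columns of `counts`.
#' @param chrom chromosome of each gene (for the CDF split); optional.
#' @param x_chrom chromosome name treated as X-linked.
#' @param active_scope passed to [call_active()].
#' @param atac_peak_sets optional named list of per-sample peak interval
#'   data.frames (consensus + merge are computed).
#' @param atac_rpk_wt,atac_rpk_ko optional peak x replicate RPK matrices for
#'   the replicate-change classification.
#' @param gene_models optional gene model data.frame for peak annotation.
#' @param yy1_peaks,h3k27ac_peaks optional peak sets for YY1 classification.
#' @param outdir optional output directory (tables + JSON manifest).
#' @return list of class `hspc_workflow` with elements `fpkm`, `active`,
#'   `deg_calls` (per population), `scope` (`deg_scope`), `cdf` (per
#'   population: fold-change vectors and K-S test), and when peak inputs are
#'   given `peaks` (consensus/merged/annotation/changes/yy1).
#' @export
run_hspc_workflow <- function(counts, lengths = NULL, meta, chrom = NULL,
                              x_chrom = "chrX",
                              active_scope = "any",
                              atac_peak_sets = NULL,
                              atac_rpk_wt = NULL, atac_rpk_ko = NULL,
                              gene_models = NULL,
                              yy1_peaks = NULL, h3k27ac_peaks = NULL,
                              outdir = NULL) {
  if (is.character(counts)) {
    cm <- read_counts_tsv(counts)
    counts <- cm$counts; lengths <- cm$lengths
  }
  counts <- .check_counts(counts)
  .stop_if(is.null(lengths), "'lengths' is required")
  .stop_if(!all(c("sample", "population", "genotype", "replicate") %in%
                  names(meta)), "'meta' needs sample/population/genotype/replicate")
  .stop_if(!identical(meta$sample, colnames(counts)),
           "'meta$sample' must match the count matrix columns in order")

  pops <- unique(meta$population)
  fpkm <- compute_fpkm(counts, lengths)
  deg_calls <- list(); active <- list(); cdf <- list()
  for (p in pops) {
    sel <- meta$population == p
    sub <- counts[, sel, drop = FALSE]
    sf <- size_factors_median_of_ratios(sub)
    norm <- sweep(sub, 2, sf, "/")
    gt <- meta$genotype[sel]
    act <- call_active(fpkm[, sel, drop = FALSE], gt, scope = active_scope)
    wt_cols <- which(gt == "WT")[order(meta$replicate[sel][gt == "WT"])]
    ko_cols <- which(gt == "KO")[order(meta$replicate[sel][gt == "KO"])]
    deg_calls[[p]] <- call_deg(norm, wt_cols, ko_cols, active = act)
    active[[p]] <- act
    if (!is.null(chrom)) {
      fc <- foldchange_cdf(fpkm[, sel, drop = FALSE][, wt_cols, drop = FALSE],
                           fpkm[, sel, drop = FALSE][, ko_cols, drop = FALSE],
                           chrom, x_chrom = x_chrom)
      ks <- if (length(fc$x) > 0L && length(fc$autosomal) > 0L)
        ks_two_sample(fc$x, fc$autosomal) else NULL
      cdf[[p]] <- list(foldchange = fc, ks = ks)
    }
  }
  scope <- scope_degs(deg_calls)

  peaks <- NULL
  if (!is.null(atac_peak_sets)) {
    cons <- consensus_peaks(atac_peak_sets)
    if (nrow(cons) == 0L)
      warning("no consensus peaks; peak annotations are empty",
              call. = FALSE)
    merged <- merge_peaks(cons, max_gap = 1000)
    ann <- if (!is.null(gene_models) && nrow(merged) > 0L)
      annotate_peaks(merged, gene_models) else NULL
    changes <- if (!is.null(atac_rpk_wt) && !is.null(atac_rpk_ko))
      classify_replicate_change(atac_rpk_wt, atac_rpk_ko) else NULL
    yy1 <- if (!is.null(yy1_peaks) && !is.null(h3k27ac_peaks) &&
                 !is.null(gene_models))
      classify_yy1_peaks(yy1_peaks, h3k27ac_peaks, gene_models) else NULL
    peaks <- list(consensus = cons, merged = merged, annotation = ann,
                  changes = changes, yy1 = yy1)
  }

  res <- structure(list(fpkm = fpkm, active = active, deg_calls = deg_calls,
                        scope = scope, cdf = cdf, peaks = peaks),
                   class = "hspc_workflow")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f_scope <- file.path(outdir, "deg_scope.tsv")
    write.table(scope$scope, f_scope, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- f_scope
    if (!is.null(peaks) && !is.null(peaks$annotation)) {
      f_ann <- file.path(outdir, "peak_annotation.tsv")
      write.table(peaks$annotation, f_ann, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f_ann)
    }
    .write_manifest(outdir, workflow = "hspc",
                    config = list(populations = pops,
                                  active_scope = active_scope),
                    row_counts = list(genes = nrow(counts),
                                      samples = ncol(counts),
                                      degs = nrow(scope$scope)),
                    files = files)
  }
  res
}

#' @export
print.hspc_workflow <- function(x, ...) {
  cat("HSPC expression workflow:", nrow(x$fpkm), "genes,",
      length(x$deg_calls), "populations\n")
  print(x$scope)
  for (p in names(x$cdf)) {
    ks <- x$cdf[[p]]$ks
    if (!is.null(ks))
      cat("  ", p, ": X vs autosomal fold-change K-S p = ",
          format(ks$p_value, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$peaks))
    cat("  consensus peaks:", nrow(x$peaks$consensus), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_manifest <- function(outdir, workflow, config, row_counts, files) {
  manifest <- list(workflow = workflow,
                   package_version = as.character(packageVersion("xcimaint")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   config = config,
                   row_counts = row_counts,
                   checksums = as.list(md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
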