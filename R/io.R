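# Plain-text readers/writers for the pipeline's tabular formats. All interval
# files are BED-style: 0-based half-open, strand in column 6.

#' Read and write allelic count tables
#'
#' TSV with columns `feature_id`, `reads_xi`, `reads_xa` (and optionally
#' `condition`).
#'
#' @param path file path.
#' @return `read_allelic_tsv()`: validated data.frame.
#' @export
read_allelic_tsv <- function(path) {
  .stop_if(!file.exists(path), "allelic count file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  .check_allelic(x)
  x
}

#' @rdname read_allelic_tsv
#' @param x allelic count data.frame.
#' @export
write_allelic_tsv <- function(x, path) {
  .check_allelic(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write count matrices with gene lengths
#'
#' TSV with columns `gene_id`, `length_bp`, then one column per sample.
#'
#' @param path file path.
#' @return `read_counts_tsv()`: list with `counts` (integer matrix, gene ids
#'   as row names) and `lengths`.
#' @export
read_counts_tsv <- function(path) {
  .stop_if(!file.exists(path), "count matrix file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .stop_if(!all(c("gene_id", "length_bp") %in% names(x)),
           "count matrix needs gene_id and length_bp columns")
  counts <- as.matrix(x[, setdiff(names(x), c("gene_id", "length_bp")),
                        drop = FALSE])
  rownames(counts) <- x$gene_id
  list(counts = counts, lengths = x$length_bp)
}

#' @rdname read_counts_tsv
#' @param counts gene x sample matrix with row names.
#' @param lengths gene lengths in bp.
#' @export
write_counts_tsv <- function(counts, lengths, path) {
  out <- data.frame(gene_id = rownames(counts), length_bp = lengths,
                    counts, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write 6-column BED files
#'
#' Columns: chrom, start, end, name, score, strand; 0-based half-open.
#' Malformed lines are reported with their line numbers.
#'
#' @param path file path.
#' @return `read_bed()`: interval data.frame.
#' @export
read_bed <- function(path) {
  .stop_if(!file.exists(path), "BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3L)
  .stop_if(length(bad) > 0L, "malformed BED line(s) (fewer than 3 fields): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default, character(1))
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  .stop_if(length(bad) > 0L, "malformed BED coordinates at line(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  data.frame(chrom = get(1, NA), start = as.integer(start),
             end = as.integer(end), name = get(4, "."),
             score = suppressWarnings(as.numeric(get(5, "0"))),
             strand = get(6, "."), stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param x interval data.frame (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @export
write_bed <- function(x, path) {
  .check_intervals(x)
  out <- data.frame(x$chrom, x$start, x$end,
                    if ("name" %in% names(x)) x$name else ".",
                    if ("score" %in% names(x)) x$score else 0L,
                    if ("strand" %in% names(x)) x$strand else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write gene model tables
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand` (0-based
#' half-open, strand `+` or `-`).
#'
#' @param path file path.
#' @return `read_gene_models()`: validated gene model data.frame.
#' @export
read_gene_models <- function(path) {
  .stop_if(!file.exists(path), "gene model file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  .check_genes(x)
  x
}

#' @rdname read_gene_models
#' @param x gene model data.frame.
#' @export
write_gene_models <- function(x, path) {
  .check_genes(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline inputs against their schemas
#'
#' Checks each supplied object (or file) against the schema its role
#' implies: allelic count tables (non-negative integer counts), count
#' matrices, BED intervals (`start < end`, `start >= 0`) and gene models
#' (strand, TSS inside the body). Violations are reported, not raised,
#' unless `strict = TRUE`. Inputs are never mutated.
#'
#' @param inputs named list; names choose the schema by prefix: `allelic*`,
#'   `counts*`, `bed*`/`peaks*`, `genes*`. Values are data.frames (or paths
#'   for `bed`/`allelic`).
#' @param strict raise an error on the first violating input.
#' @return data.frame with columns `input` and `violation` (zero rows when
#'   everything is valid).
#' @export
validate_inputs <- function(inputs, strict = FALSE) {
  .stop_if(!is.list(inputs) || is.null(names(inputs)),
           "'inputs' must be a named list")
  out <- data.frame(input = character(0), violation = character(0),
                    stringsAsFactors = FALSE)
  note <- function(nm, msg) rbind(out, data.frame(input = nm, violation = msg,
                                                  stringsAsFactors = FALSE))
  for (nm in names(inputs)) {
    x <- inputs[[nm]]
    res <- tryCatch({
      if (is.character(x) && length(x) == 1L) {
        if (grepl("^(bed|peaks)", nm)) x <- read_bed(x)
        else if (grepl("^allelic", nm)) x <- read_allelic_tsv(x)
        else if (grepl("^counts", nm)) x <- read_counts_tsv(x)
        else if (grepl("^genes", nm)) x <- read_gene_models(x)
        else stop("unknown input role for '", nm, "'")
      } else {
        if (grepl("^allelic", nm)) .check_allelic(x)
        else if (grepl("^counts", nm)) .check_counts(as.matrix(
          x[, setdiff(names(x), c("gene_id", "length_bp")), drop = FALSE]))
        else if (grepl("^(bed|peaks)", nm)) .check_intervals(x)
        else if (grepl("^genes", nm)) .check_genes(x)
        else stop("unknown input role for '", nm, "'")
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      out <- note(nm, res)
      if (strict) stop("validation failure for '", nm, "': ", res,
                       call. = FALSE)
    }
  }
  out
}

#' Read a workflow configuration from YAML
#'
#' Thin wrapper: loads a YAML file into a named list and checks that any
#' entries ending in `_path` point at existing files.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  .stop_if(!file.exists(path), "config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (nm in grep("_path$", names(cfg), value = TRUE))
    .stop_if(!file.exists(cfg[[nm]]),
             "configured path does not exist: ", cfg[[nm]], " (", nm, ")")
  cfg
}
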