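#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the probability-mass criterion: the sum
#' of hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability. Probabilities are
#' evaluated in log space; tables whose probability is within a relative
#' tolerance of `tie_tol` of the observed one count as ties and are included
#' (the convention of the common implementations).
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative integer
#'   counts; rows and columns are the two binary classifications.
#' @param tie_tol relative tolerance for floating-point ties (default 1e-7).
#' @return An object of class `assoc_test`: list with `statistic` (the
#'   observed count in cell \[1,1\]), `p_value`, `test_name`, `tails` and
#'   `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(14, 21, 3, 313), nrow = 2))
#' @export
fisher_exact_2x2 <- function(tab, tie_tol = 1e-7) {
  tab <- .check_2x2(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0L, c1 - r2):min(r1, c1)
  lp <- dhyper(k, r1, r2, c1, log = TRUE)
  lobs <- dhyper(tab[1, 1], r1, r2, c1, log = TRUE)
  p <- min(1, sum(exp(lp[lp <= lobs + log1p(tie_tol)])))
  .assoc_test(statistic = tab[1, 1], p_value = p,
              test_name = "Fisher exact test", table = tab)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Pearson statistic `sum((O - E)^2 / E)` on 1 degree of freedom with an
#' upper-tail p-value; no continuity correction by default.
#'
#' @inheritParams fisher_exact_2x2
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return An `assoc_test` object with the chi-squared `statistic`.
#' @examples
#' chi_squared_2x2(matrix(c(50, 10, 10, 50), nrow = 2))
#' @export
chi_squared_2x2 <- function(tab, correct = FALSE) {
  tab <- .check_2x2(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  .stop_if(any(e == 0), "chi-squared test undefined: a margin is zero")
  dev <- abs(tab - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  .assoc_test(statistic = stat,
              p_value = pchisq(stat, df = 1, lower.tail = FALSE),
              test_name = if (correct) "chi-squared test (Yates-corrected)"
                          else "chi-squared test",
              table = tab)
}

#' Choose between the exact and the chi-squared test
#'
#' The convention applied to peak-category comparisons: the chi-squared test
#' when the number of units exceeds 300, the Fisher exact test otherwise
#' (boundary 300 itself still uses Fisher).
#'
#' @param n_units number of units (e.g. peaks) entering the table.
#' @param threshold switch point (default 300, strict `>`).
#' @return `"chi_squared"` or `"fisher"`.
#' @examples
#' choose_test(300) # fisher
#' choose_test(301) # chi_squared
#' @export
choose_test <- function(n_units, threshold = 300) {
  .stop_if(!is.numeric(n_units) || length(n_units) != 1L || n_units < 0,
           "'n_units' must be a single non-negative number")
  if (n_units > threshold) "chi_squared" else "fisher"
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided comparison of two empirical distributions, e.g. the expression
#' fold-change CDFs of X-linked versus autosomal genes. The statistic is
#' `D = sup |F_x - F_y|`; the p-value is exact (full enumeration over label
#' assignments) when `min(n, m) <= 10` and asymptotic otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @return An `assoc_test` object with `statistic` = D.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50, mean = 1))
#' @export
ks_two_sample <- function(x, y) {
  .stop_if(length(x) == 0L || length(y) == 0L,
           "both samples must be non-empty")
  .stop_if(any(!is.finite(x)) || any(!is.finite(y)),
           "samples must be finite numeric vectors")
  exact <- min(length(x), length(y)) <= 10L
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided",
                                 exact = exact))
  .assoc_test(statistic = unname(kt$statistic), p_value = kt$p.value,
              test_name = "Kolmogorov-Smirnov test")
}

#' Association between XCI escape and Xist dependence
#'
#' Builds the 2x2 table cross-classifying XCI status (escape/subjective) by
#' Xist dependence (dependent/independent) from a classification table and
#' applies the two-sided Fisher exact test (or the chi-squared test when the
#' number of features exceeds `chi_threshold` and `switch_test = TRUE`).
#'
#' When a row or column of the table is empty the association is degenerate;
#' a warning is issued and p = 1 is reported by convention.
#'
#' @param cls an `xci_classification` table from [run_allelic_pipeline()], or
#'   any data.frame with columns `feature_id`, `xci_status`, `dependence`.
#' @param exclude optional feature ids to drop (e.g. `"Xist"`, whose own
#'   deletion makes its dependence call uninformative).
#' @param switch_test if `TRUE`, use [choose_test()] on the number of features
#'   to pick between Fisher and chi-squared; default `FALSE` (always Fisher).
#' @param chi_threshold passed to [choose_test()].
#' @return list of class `xci_association` with elements `table` (2x2 matrix,
#'   rows escape/subjective, columns dependent/independent) and `test`
#'   (an `assoc_test`).
#' @examples
#' sim <- simulate_allelic_counts(allelic_sim_config(seed = 7))
#' cls <- run_allelic_pipeline(sim$wt, sim$mut)
#' escape_dependence_association(cls)
#' @export
escape_dependence_association <- function(cls, exclude = NULL,
                                          switch_test = FALSE,
                                          chi_threshold = 300) {
  .stop_if(!is.data.frame(cls) ||
             !all(c("feature_id", "xci_status", "dependence") %in% names(cls)),
           "'cls' must have columns feature_id, xci_status, dependence")
  .stop_if(nrow(cls) == 0L, "classification table is empty")
  if (!is.null(exclude)) cls <- cls[!cls$feature_id %in% exclude, , drop = FALSE]
  esc <- cls$xci_status == "escape"
  dep <- cls$dependence == "dependent"
  tab <- matrix(c(sum(esc & dep), sum(!esc & dep),
                  sum(esc & !dep), sum(!esc & !dep)), nrow = 2,
                dimnames = list(c("escape", "subjective"),
                                c("dependent", "independent")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table (empty row or column); p = 1",
            call. = FALSE)
    test <- .assoc_test(statistic = NA_real_, p_value = 1,
                        test_name = "Fisher exact test (degenerate table)",
                        table = tab)
  } else if (switch_test &&
             choose_test(nrow(cls), chi_threshold) == "chi_squared") {
    test <- chi_squared_2x2(tab)
  } else {
    test <- fisher_exact_2x2(tab)
  }
  structure(list(table = tab, test = test), class = "xci_association")
}

#' @export
print.xci_association <- function(x, ...) {
  cat("XCI escape x Xist dependence association\n")
  print(x$table)
  print(x$test)
  invisible(x)
}

.check_2x2 <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (is.vector(tab) && length(tab) == 4L) tab <- matrix(tab, nrow = 2)
  .stop_if(!is.matrix(tab) || !all(dim(tab) == c(2L, 2L)),
           "'tab' must be a 2x2 table")
  .stop_if(any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)),
           "table entries must be non-negative integers")
  .stop_if(sum(tab) == 0, "table total must be positive")
  storage.mode(tab) <- "double"
  tab
}

.assoc_test <- function(statistic, p_value, test_name, table = NULL) {
  structure(list(statistic = statistic, p_value = p_value,
                 test_name = test_name, tails = "two-sided", table = table),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$tails, " ", x$test_name, ": ", sep = "")
  if (!is.na(x$statistic)) cat("statistic = ", signif(x$statistic, 4), ", ",
                               sep = "")
  cat("p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
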