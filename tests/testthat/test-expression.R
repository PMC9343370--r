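test_that("FPKM formula, invariances and totals", {
  m <- matrix(c(1000, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  # pad the sample total to 1e6 via gene b
  m["b", 1] <- 1e6 - 1000
  f <- compute_fpkm(m, lengths = c(2000, 1000))
  expect_equal(f["a", 1], 500)
  expect_equal(compute_fpkm(matrix(c(0, 10), 2), c(100, 100))[1, 1], 0)

  set.seed(21)
  counts <- matrix(rpois(200, 40), 50, 4,
                   dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:4)))
  len <- sample(500:5000, 50)
  f <- compute_fpkm(counts, len)
  # doubling a sample's counts (and thereby its total) leaves FPKM unchanged
  c2 <- counts; c2[, 2] <- c2[, 2] * 2
  expect_equal(compute_fpkm(c2, len)[, 2], f[, 2])
  # per sample, sum(FPKM * length_kb) = 1e6
  expect_equal(unname(colSums(f * len / 1000)), rep(1e6, 4),
               tolerance = 1e-6)
  expect_error(compute_fpkm(counts, c(0, len[-1])), "positive")
})

test_that("median-of-ratios size factors: closed forms and DESeq2 agreement", {
  m <- matrix(rpois(80, 60) + 1, 20, 4)
  rownames(m) <- sprintf("g%d", 1:20)
  colnames(m) <- sprintf("s%d", 1:4)
  # identical columns -> all factors 1
  sf_id <- size_factors_median_of_ratios(cbind(s1 = m[, 1], s2 = m[, 1]))
  expect_equal(unname(sf_id), c(1, 1))
  # one column exactly doubled: its factor is 2x the others'
  d <- cbind(a = m[, 1], b = m[, 1] * 2)
  sf <- size_factors_median_of_ratios(d)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  # single gene, counts (2, 8): factors proportional to (0.5, 2)
  sf1 <- size_factors_median_of_ratios(matrix(c(2, 8), 1, 2,
                                              dimnames = list("g", c("x", "y"))))
  expect_equal(unname(sf1), c(0.5, 2))
  # independent reference implementation
  expect_equal(unname(size_factors_median_of_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
  expect_error(size_factors_median_of_ratios(
    matrix(c(0, 1, 1, 0), 2, 2)), "normalization error")
})

test_that("activity flag is inclusive at FPKM 1 and scope-aware", {
  fpkm <- rbind(g1 = c(1, 1, 0.2, 0.2), g2 = c(0, 0, 0, 0),
                g3 = c(0.99, 0.99, 0.99, 0.99), g4 = c(0.5, 0.5, 3, 3))
  gt <- c("WT", "WT", "KO", "KO")
  expect_equal(unname(call_active(fpkm, gt, scope = "any")),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(call_active(fpkm, gt, scope = "both")),
               c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(call_active(fpkm, gt, scope = "wt")),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("replicate-consistent DEG calls with strict inequalities", {
  m <- rbind(up = c(100, 110, 150, 160),
             incons = c(100, 110, 150, 90),
             tie = c(100, 100, 100, 100),
             down = c(100, 110, 50, 60),
             inact = c(100, 110, 150, 160))
  act <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  d <- call_deg(m, wt_cols = 1:2, ko_cols = 3:4, active = act)
  expect_equal(d$direction, c("up", "non", "non", "down", "non"))
  # normalization idempotence: rescaling samples by their own size factors
  set.seed(8)
  counts <- matrix(rpois(400, 80) + 1, 100, 4,
                   dimnames = list(sprintf("g%d", 1:100), NULL))
  sf <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  d1 <- call_deg(norm, 1:2, 3:4)
  renorm <- sweep(norm, 2, size_factors_median_of_ratios(norm), "/")
  expect_equal(call_deg(renorm, 1:2, 3:4)$direction, d1$direction)
  expect_error(call_deg(m, 1:2, 3:4, active = TRUE), "per gene")
})

test_that("cDEG/lsDEG scoping rules and set identities", {
  mk <- function(dirs) data.frame(gene_id = sprintf("g%d", seq_along(dirs)),
                                  direction = dirs, active = TRUE)
  calls <- list(p1 = mk(c("up", "up", "up", "non", "non")),
                p2 = mk(c("up", "up", "down", "non", "non")),
                p3 = mk(c("up", "non", "non", "non", "non")))
  sc <- scope_degs(calls)$scope
  expect_equal(sc$scope[sc$gene_id == "g1"], "cDEG")   # up in all 3
  expect_equal(sc$scope[sc$gene_id == "g2"], "lsDEG")  # up in 2 of 3
  expect_equal(sc$scope[sc$gene_id == "g3"], "lsDEG")  # direction-discordant
  expect_false("g4" %in% sc$gene_id)
  # identities: cDEG subset of every population's DEGs; partition of union
  set.seed(13)
  for (rep in 1:25) {
    dirs <- replicate(3, sample(c("up", "down", "non"), 40, replace = TRUE),
                      simplify = FALSE)
    calls <- setNames(lapply(dirs, mk), c("a", "b", "c"))
    res <- scope_degs(calls)$scope
    cdeg <- res$gene_id[res$scope == "cDEG"]
    lsdeg <- res$gene_id[res$scope == "lsDEG"]
    degs <- lapply(calls, function(d) d$gene_id[d$direction != "non"])
    expect_length(intersect(cdeg, lsdeg), 0)
    for (d in degs) expect_true(all(cdeg %in% d))
    expect_setequal(c(cdeg, lsdeg), unique(unlist(degs)))
  }
})

test_that("signature genes: rule application and disjointness", {
  fp <- rbind(g1 = c(5, 0.2, 0.1), g2 = c(5, 2, 0.1), g3 = c(5, 0.2, 0.1),
              g4 = c(0.5, 0.2, 0.1))
  colnames(fp) <- c("CMP", "GMP", "MEP")
  pv <- matrix(0.01, 4, 3, dimnames = dimnames(fp))
  pv["g3", "CMP"] <- 0.2
  sig <- signature_genes(fp, pv)
  expect_equal(sig$CMP, "g1")          # g2 active elsewhere, g3 not
  expect_length(sig$GMP, 0)            # significant, also fails FPKM rule
  expect_length(intersect(sig$CMP, c(sig$GMP, sig$MEP)), 0)
  expect_error(signature_genes(fp[, 1:2], pv[, 1:2]), "three populations")
})

test_that("keyword grouping is case-insensitive substring matching", {
  ann <- data.frame(gene_id = c("a", "a", "b", "c"),
                    term = c("Mitotic Cell Cycle", "ribosome",
                             "type I interferon signaling", "transport"))
  g <- keyword_group(ann, xci_keyword_sets())
  expect_true(g$cell_cycle[g$gene_id == "a"])
  expect_true(g$immune[g$gene_id == "b"])
  expect_false(any(unlist(g[g$gene_id == "c", -1])))
  expect_error(keyword_group(ann, list()), "non-empty")
})

test_that("fold-change vectors: filtering and split by chromosome class", {
  fw <- cbind(r1 = c(2, 0.5, 4, 0), r2 = c(2, 0.5, 4, 0))
  fk <- cbind(r1 = c(2, 0.5, 8, 2), r2 = c(2, 0.5, 8, 2))
  rownames(fw) <- rownames(fk) <- c("gx", "glow", "ga", "gz")
  chrom <- c("chrX", "chrX", "chr5", "chr5")
  expect_warning(fc <- foldchange_cdf(fw, fk, chrom), "zero WT mean")
  expect_equal(unname(fc$x), 1)            # glow filtered, gz dropped
  expect_equal(unname(fc$autosomal), 2)
  expect_equal(fc$n_dropped_zero_wt, 1)
  # identical genotypes: all fold changes 1, K-S p = 1
  fc1 <- foldchange_cdf(fw[1:3, ], fw[1:3, ], chrom[1:3])
  expect_true(all(c(fc1$x, fc1$autosomal) == 1))
  expect_equal(ks_two_sample(fc1$x, fc1$autosomal)$p_value, 1)
})

test_that("planted X-linked shift is detected by the K-S comparison", {
  set.seed(17)
  n <- 300
  fw <- matrix(rlnorm(2 * n * 2, log(10), 0.3), 2 * n, 2)
  shift <- rep(c(1.2, 1), each = n) # +20% on the X
  fk <- fw * shift * matrix(rlnorm(2 * n * 2, 0, 0.05), 2 * n, 2)
  rownames(fw) <- rownames(fk) <- sprintf("g%d", 1:(2 * n))
  chrom <- rep(c("chrX", "chr1"), each = n)
  fc <- foldchange_cdf(fw, fk, chrom)
  r <- ks_two_sample(fc$x, fc$autosomal)
  expect_lt(r$p_value, 0.05)
  expect_gt(median(fc$x), median(fc$autosomal)) # right-shifted X CDF
})
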