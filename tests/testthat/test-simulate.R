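test_that("allelic simulator: determinism, degenerate mixture, validation", {
  cfg <- allelic_sim_config(n_genes = 100, seed = 5)
  s1 <- simulate_allelic_counts(cfg)
  s2 <- simulate_allelic_counts(cfg)
  expect_identical(s1, s2)
  # a different seed changes the draw
  s3 <- simulate_allelic_counts(allelic_sim_config(n_genes = 100, seed = 6))
  expect_false(identical(s1$wt$reads_xi, s3$wt$reads_xi))
  # escape_fraction = 0: no escape labels
  s0 <- simulate_allelic_counts(allelic_sim_config(n_genes = 60,
                                                   escape_fraction = 0,
                                                   seed = 2))
  expect_false(any(s0$truth$true_escape))
  # generator does not perturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_allelic_counts(cfg)); after <- rnorm(3)
  expect_identical(before, after)
  expect_error(allelic_sim_config(escape_fraction = 1.2), "proportion")
  expect_error(allelic_sim_config(escape_xi_fraction_range = c(0.01, 0.3)),
               "0.05/1.05")
  expect_error(allelic_sim_config(dependent_shift = 0.01), ">= 0.03")
  expect_error(allelic_sim_config(escape_xi_fraction_range = c(0.3, 0.5),
                                  dependent_shift = 0.6), "above 1")
})

test_that("empirical Xi fraction converges to truth at high depth", {
  sim <- simulate_allelic_counts(
    allelic_sim_config(n_genes = 200, depth_mean = 1e5,
                       depth_dispersion = 0, seed = 8))
  emp <- sim$wt$reads_xi / (sim$wt$reads_xi + sim$wt$reads_xa)
  expect_lt(max(abs(emp - sim$truth$true_xi_fraction_wt)), 0.01)
  emp_m <- sim$mut$reads_xi / (sim$mut$reads_xi + sim$mut$reads_xa)
  expect_lt(max(abs(emp_m - sim$truth$true_xi_fraction_mut)), 0.01)
})

test_that("end-to-end label recovery at depth 1e4 with shift 0.1", {
  sim <- simulate_allelic_counts(
    allelic_sim_config(n_genes = 500, depth_mean = 1e4,
                       dependent_shift = 0.1, seed = 12))
  cls <- run_allelic_pipeline(sim$wt, sim$mut)
  tr <- sim$truth[match(cls$feature_id, sim$truth$gene_id), ]
  expect_gte(mean((cls$xci_status == "escape") == tr$true_escape), 0.95)
  expect_gte(mean((cls$dependence == "dependent") == tr$true_dependent),
             0.95)
})

test_that("expression simulator: determinism, null effect, planted design", {
  cfg <- expression_sim_config(n_genes = 200, n_cdeg_up = 10,
                               n_cdeg_down = 5, n_lsdeg_per_population = 10,
                               seed = 3)
  e1 <- simulate_expression_matrix(cfg)
  e2 <- simulate_expression_matrix(cfg)
  expect_identical(e1, e2)
  expect_equal(dim(e1$counts), c(200L, 12L)) # 3 pops x 2 genotypes x 2 reps
  expect_identical(e1$meta$sample, colnames(e1$counts))
  # null effect still emits the planted label table
  e0 <- simulate_expression_matrix(
    expression_sim_config(n_genes = 100, effect_log2fc = 0, n_cdeg_up = 5,
                          n_cdeg_down = 5, n_lsdeg_per_population = 5,
                          seed = 4))
  expect_equal(sum(e0$labels$scope == "cDEG"), 10)
  # each lsDEG is assigned exactly one population
  ls <- e1$labels[e1$labels$scope == "lsDEG", ]
  expect_false(any(is.na(ls$population)))
  expect_equal(nrow(ls), 30)
  expect_error(expression_sim_config(n_genes = 10, n_cdeg_up = 20),
               "exceed")
})

test_that("planted cDEGs are recovered by the DEG/scoping pipeline", {
  cfg <- expression_sim_config(n_genes = 500, n_cdeg_up = 25,
                               n_cdeg_down = 15,
                               n_lsdeg_per_population = 20,
                               effect_log2fc = 2, dispersion = 0.02,
                               seed = 19)
  sim <- simulate_expression_matrix(cfg)
  wf <- run_hspc_workflow(sim$counts, sim$lengths, sim$meta)
  sc <- wf$scope$scope
  planted <- sim$labels[sim$labels$scope == "cDEG", ]
  hit <- sc[match(planted$gene_id, sc$gene_id), ]
  recovered <- !is.na(hit$scope) & hit$scope == "cDEG" &
    hit$direction == planted$direction
  expect_gte(mean(recovered), 0.95)
})

test_that("interval simulator honours placement policies deterministically", {
  cfg <- interval_sim_config(
    n_genes = 30, chrom_length = 6e6, seed = 23,
    peak_sets = list(
      prom = list(n_peaks = 40L, width_range = c(200, 600),
                  placement = "promoter"),
      enh = list(n_peaks = 40L, width_range = c(200, 600),
                 placement = "enhancer_band"),
      rnd = list(n_peaks = 50L, width_range = c(100, 1000),
                 placement = "random")))
  iv1 <- simulate_intervals(cfg)
  iv2 <- simulate_intervals(cfg)
  expect_identical(iv1, iv2)
  genes <- iv1$genes
  # genes are non-overlapping and within the chromosome
  o <- order(genes$start)
  expect_true(all(genes$end[o][-nrow(genes)] <= genes$start[o][-1]))
  expect_true(all(genes$start >= 0 & genes$end <= cfg$chrom_length))
  # promoter placement -> 100% classified promoter
  r <- classify_yy1_peaks(iv1$peaks$prom, iv1$peaks$enh_h3k27ac, genes)
  expect_true(all(r$class == "promoter"))
  # enhancer-band placement with co-placed H3K27ac -> 100% enhancer
  r2 <- classify_yy1_peaks(iv1$peaks$enh, iv1$peaks$enh_h3k27ac, genes)
  expect_true(all(r2$class == "enhancer"))
  # and the oracle agrees
  expect_identical(r2$class,
                   oracle_yy1_class(iv1$peaks$enh, iv1$peaks$enh_h3k27ac,
                                    genes))
  expect_error(interval_sim_config(n_genes = 1000, chrom_length = 1e5),
               "capacity")
})
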