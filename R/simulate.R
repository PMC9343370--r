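# Synthetic-data generators. Each generator seeds its own RNG stream from the
# config and restores the caller's RNG state, so identical config => identical
# output regardless of what else has been simulated.

.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.check_prop <- function(x, nm) {
  .stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
             x < 0 || x > 1, "'", nm, "' must be a proportion in [0, 1]")
}

#' Configuration for the allelic count simulator
#'
#' Defaults mirror the observed wild-type MEF regime: 352 allelically
#' analyzable X-linked genes of which a fraction 18/352 escape XCI, escape
#' genes Xist-dependent with probability 14/18 and subjective genes with
#' probability 21/334, so a default simulation reproduces a strong
#' escape-by-dependence association.
#'
#' @param n_genes number of genes to simulate.
#' @param escape_fraction probability that a gene escapes XCI.
#' @param p_dependent_given_escape,p_dependent_given_subjective probability
#'   of Xist dependence given escape status.
#' @param depth_mean expected allelic read depth per gene per condition.
#' @param depth_dispersion negative-binomial dispersion of the depth (0
#'   degenerates to Poisson).
#' @param silenced_xi_fraction wild-type Xi read fraction of subjective genes
#'   (default 0.005 — nearly fully silenced).
#' @param escape_xi_fraction_range range of wild-type Xi read fractions for
#'   escape genes, drawn uniformly; the lower bound must be at least
#'   0.05/1.05 so planted escape genes satisfy the Xi/Xa >= 0.05 ratio rule
#'   in expectation.
#' @param dependent_shift d-score increase applied to Xist-dependent genes in
#'   the mutant condition (>= 0.03 so the planted signal is detectable by the
#'   classification rule).
#' @param seed integer RNG seed.
#' @return validated list of class `allelic_sim_config`.
#' @export
allelic_sim_config <- function(n_genes = 352L,
                               escape_fraction = 18 / 352,
                               p_dependent_given_escape = 14 / 18,
                               p_dependent_given_subjective = 21 / 334,
                               depth_mean = 1e4,
                               depth_dispersion = 0.3,
                               silenced_xi_fraction = 0.005,
                               escape_xi_fraction_range = c(0.05 / 1.05, 0.4),
                               dependent_shift = 0.1,
                               seed = 1L) {
  .stop_if(n_genes < 1 || n_genes != round(n_genes),
           "'n_genes' must be a positive integer")
  .check_prop(escape_fraction, "escape_fraction")
  .check_prop(p_dependent_given_escape, "p_dependent_given_escape")
  .check_prop(p_dependent_given_subjective, "p_dependent_given_subjective")
  .check_prop(silenced_xi_fraction, "silenced_xi_fraction")
  .stop_if(depth_mean <= 0, "'depth_mean' must be positive")
  .stop_if(depth_dispersion < 0, "'depth_dispersion' must be >= 0")
  r <- escape_xi_fraction_range
  .stop_if(length(r) != 2L || r[1] > r[2] ||
             r[1] < 0.05 / 1.05 - .XCI_EPS || r[2] > 0.5,
           "'escape_xi_fraction_range' must lie within [0.05/1.05, 0.5]")
  .stop_if(dependent_shift < 0.03,
           "'dependent_shift' must be >= 0.03 to be detectable by design")
  .stop_if(r[2] + dependent_shift > 1,
           "'dependent_shift' would push the mutant Xi fraction above 1")
  structure(list(n_genes = as.integer(n_genes),
                 escape_fraction = escape_fraction,
                 p_dependent_given_escape = p_dependent_given_escape,
                 p_dependent_given_subjective = p_dependent_given_subjective,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 silenced_xi_fraction = silenced_xi_fraction,
                 escape_xi_fraction_range = r,
                 dependent_shift = dependent_shift,
                 seed = as.integer(seed)),
            class = "allelic_sim_config")
}

.rdepth <- function(n, mean, dispersion) {
  if (dispersion == 0) rpois(n, mean)
  else rnbinom(n, mu = mean, size = 1 / dispersion)
}

#' Simulate allelic count tables with ground truth
#'
#' Per gene, the total allelic depth in each condition is drawn from a
#' negative-binomial law with mean `depth_mean` (Poisson when the dispersion
#' is 0), and Xi reads are drawn binomially with the gene's true Xi read
#' fraction. Escape genes draw their wild-type Xi fraction uniformly from
#' `escape_xi_fraction_range`; subjective genes sit at
#' `silenced_xi_fraction`. Xist-dependent genes have their mutant Xi fraction
#' raised by `dependent_shift`, which raises the expected d-score by the
#' same amount.
#'
#' @param cfg an [allelic_sim_config()].
#' @return list with `wt` and `mut` allelic count data.frames (`feature_id`,
#'   `reads_xi`, `reads_xa`, `condition`) and `truth` (`gene_id`,
#'   `true_escape`, `true_dependent`, `true_xi_fraction_wt`,
#'   `true_xi_fraction_mut`).
#' @examples
#' sim <- simulate_allelic_counts(allelic_sim_config(n_genes = 20, seed = 3))
#' head(sim$truth)
#' @export
simulate_allelic_counts <- function(cfg) {
  .stop_if(!inherits(cfg, "allelic_sim_config"),
           "'cfg' must come from allelic_sim_config()")
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    ids <- sprintf("gene%04d", seq_len(n))
    esc <- runif(n) < cfg$escape_fraction
    f_wt <- ifelse(esc,
                   runif(n, cfg$escape_xi_fraction_range[1],
                         cfg$escape_xi_fraction_range[2]),
                   cfg$silenced_xi_fraction)
    p_dep <- ifelse(esc, cfg$p_dependent_given_escape,
                    cfg$p_dependent_given_subjective)
    dep <- runif(n) < p_dep
    f_mut <- pmin(1, f_wt + cfg$dependent_shift * dep)
    depth_wt <- .rdepth(n, cfg$depth_mean, cfg$depth_dispersion)
    depth_mut <- .rdepth(n, cfg$depth_mean, cfg$depth_dispersion)
    xi_wt <- rbinom(n, depth_wt, f_wt)
    xi_mut <- rbinom(n, depth_mut, f_mut)
    list(wt = data.frame(feature_id = ids, reads_xi = xi_wt,
                         reads_xa = depth_wt - xi_wt, condition = "WT",
                         stringsAsFactors = FALSE),
         mut = data.frame(feature_id = ids, reads_xi = xi_mut,
                          reads_xa = depth_mut - xi_mut, condition = "MUT",
                          stringsAsFactors = FALSE),
         truth = data.frame(gene_id = ids, true_escape = esc,
                            true_dependent = dep,
                            true_xi_fraction_wt = f_wt,
                            true_xi_fraction_mut = f_mut,
                            stringsAsFactors = FALSE))
  })
}

#' Configuration for the multi-population expression simulator
#'
#' Emulates the two-replicate, three-population design of the HSPC
#' experiment: for each population, WT and KO genotypes with `n_replicates`
#' count columns each. Planted common DEGs (cDEGs) are shifted in the same
#' direction in every population; planted lineage-specific DEGs (lsDEGs) in
#' exactly one.
#'
#' @param n_genes number of genes.
#' @param n_populations number of cell populations (default 3).
#' @param n_replicates biological replicates per genotype (default 2).
#' @param n_cdeg_up,n_cdeg_down planted shared DEG counts.
#' @param n_lsdeg_per_population planted lineage-specific DEGs per
#'   population (random direction).
#' @param effect_log2fc planted |log2 fold change| (> 0 for a real effect; 0
#'   gives a null simulation).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param library_size expected total counts per sample.
#' @param populations population names.
#' @param seed integer RNG seed.
#' @return validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 1000L, n_populations = 3L,
                                  n_replicates = 2L, n_cdeg_up = 30L,
                                  n_cdeg_down = 10L,
                                  n_lsdeg_per_population = 50L,
                                  effect_log2fc = 2, dispersion = 0.05,
                                  library_size = 5e6,
                                  populations = NULL, seed = 1L) {
  .stop_if(n_genes < 1, "'n_genes' must be positive")
  .stop_if(n_populations < 2, "need at least two populations")
  .stop_if(n_replicates < 1, "'n_replicates' must be >= 1")
  .stop_if(effect_log2fc < 0, "'effect_log2fc' must be >= 0")
  .stop_if(dispersion < 0, "'dispersion' must be >= 0")
  .stop_if(library_size <= 0, "'library_size' must be positive")
  n_planted <- n_cdeg_up + n_cdeg_down +
    n_populations * n_lsdeg_per_population
  .stop_if(n_planted > n_genes,
           "planted DEG counts exceed the number of genes")
  if (is.null(populations))
    populations <- c("LSKpos", "LSKneg", "Linneg",
                     paste0("pop", seq_len(max(0, n_populations - 3))))[
                       seq_len(n_populations)]
  .stop_if(length(populations) != n_populations,
           "'populations' must name every population")
  structure(list(n_genes = as.integer(n_genes),
                 n_populations = as.integer(n_populations),
                 n_replicates = as.integer(n_replicates),
                 n_cdeg_up = as.integer(n_cdeg_up),
                 n_cdeg_down = as.integer(n_cdeg_down),
                 n_lsdeg_per_population = as.integer(n_lsdeg_per_population),
                 effect_log2fc = effect_log2fc,
                 dispersion = dispersion,
                 library_size = library_size,
                 populations = populations,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate multi-population expression count matrices
#'
#' Counts are drawn per gene, sample and population around
#' genotype-specific negative-binomial means. Planted cDEGs are shifted by
#' `2^effect_log2fc` in the KO genotype in every population (up or down);
#' each planted lsDEG is shifted in exactly one population. Planted DEGs get
#' a floor on their baseline mean so the planted signal is not drowned by
#' shot noise at typical depths.
#'
#' @param cfg an [expression_sim_config()].
#' @return list with `counts` (gene x sample integer matrix), `lengths`
#'   (gene lengths in bp), `meta` (data.frame `sample`, `population`,
#'   `genotype`, `replicate`) and `labels` (`gene_id`, `scope` in
#'   `{cDEG, lsDEG, none}`, `direction`, `population` — `NA` for cDEGs).
#' @export
simulate_expression_matrix <- function(cfg) {
  .stop_if(!inherits(cfg, "expression_sim_config"),
           "'cfg' must come from expression_sim_config()")
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    ids <- sprintf("gene%05d", seq_len(n))
    lengths <- round(runif(n, 500, 5000))
    mu0 <- rlnorm(n, meanlog = log(50), sdlog = 1.2)

    planted <- sample.int(n, cfg$n_cdeg_up + cfg$n_cdeg_down +
                            cfg$n_populations * cfg$n_lsdeg_per_population)
    mu0[planted] <- pmax(mu0[planted], 50)
    i_up <- planted[seq_len(cfg$n_cdeg_up)]
    i_down <- planted[cfg$n_cdeg_up + seq_len(cfg$n_cdeg_down)]
    i_ls <- planted[cfg$n_cdeg_up + cfg$n_cdeg_down +
                      seq_len(cfg$n_populations * cfg$n_lsdeg_per_population)]
    ls_pop <- rep(seq_len(cfg$n_populations),
                  each = cfg$n_lsdeg_per_population)
    ls_dir <- sample(c("up", "down"), length(i_ls), replace = TRUE)

    fc <- 2^cfg$effect_log2fc
    mu0 <- mu0 / sum(mu0 * 1) * cfg$library_size / 1  # scale to library size
    meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        genotype = c("WT", "KO"),
                        population = cfg$populations,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$sample <- paste(meta$population, meta$genotype, meta$replicate,
                         sep = "_")
    meta <- meta[, c("sample", "population", "genotype", "replicate")]
    counts <- matrix(0L, n, nrow(meta), dimnames = list(ids, meta$sample))
    for (s in seq_len(nrow(meta))) {
      mu <- mu0
      if (meta$genotype[s] == "KO") {
        mu[i_up] <- mu[i_up] * fc
        mu[i_down] <- mu[i_down] / fc
        p_idx <- match(meta$population[s], cfg$populations)
        sel <- ls_pop == p_idx
        mu[i_ls[sel]] <- mu[i_ls[sel]] *
          ifelse(ls_dir[sel] == "up", fc, 1 / fc)
      }
      counts[, s] <- if (cfg$dispersion == 0) rpois(n, mu)
                     else rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    }
    labels <- data.frame(gene_id = ids, scope = "none",
                         direction = NA_character_,
                         population = NA_character_,
                         stringsAsFactors = FALSE)
    labels$scope[i_up] <- "cDEG"; labels$direction[i_up] <- "up"
    labels$scope[i_down] <- "cDEG"; labels$direction[i_down] <- "down"
    labels$scope[i_ls] <- "lsDEG"; labels$direction[i_ls] <- ls_dir
    labels$population[i_ls] <- cfg$populations[ls_pop]
    list(counts = counts, lengths = lengths, meta = meta, labels = labels)
  })
}

#' Configuration for the gene/peak interval simulator
#'
#' @param n_genes number of non-overlapping genes on the synthetic
#'   chromosome.
#' @param chrom_length chromosome length in bp.
#' @param gene_length_range gene length range in bp.
#' @param peak_sets named list; each element a list with `n_peaks`,
#'   `width_range` and `placement` (one of `"promoter"`, `"enhancer_band"`,
#'   `"random"`). Enhancer-band sets also generate a co-placed H3K27ac set
#'   named `<set>_h3k27ac`.
#' @param chrom chromosome name.
#' @param seed integer RNG seed.
#' @return validated list of class `interval_sim_config`.
#' @export
interval_sim_config <- function(n_genes = 50L, chrom_length = 5e6,
                                gene_length_range = c(2000, 20000),
                                peak_sets = list(
                                  atac = list(n_peaks = 100L,
                                              width_range = c(200, 800),
                                              placement = "random")),
                                chrom = "chrS", seed = 1L) {
  .stop_if(n_genes < 1, "'n_genes' must be positive")
  .stop_if(gene_length_range[1] <= 0 ||
             gene_length_range[1] > gene_length_range[2],
           "'gene_length_range' must be a positive increasing interval")
  margin <- 130000
  .stop_if(n_genes * gene_length_range[2] * 1.25 + 2 * margin > chrom_length,
           "generation error: requested genes exceed chromosome capacity")
  .stop_if(!is.list(peak_sets) || is.null(names(peak_sets)),
           "'peak_sets' must be a named list")
  for (ps in peak_sets) {
    .stop_if(!all(c("n_peaks", "width_range", "placement") %in% names(ps)),
             "each peak set needs n_peaks, width_range, placement")
    .stop_if(!ps$placement %in% c("promoter", "enhancer_band", "random"),
             "placement must be promoter, enhancer_band or random")
    .stop_if(ps$width_range[1] <= 0 ||
               ps$width_range[1] > ps$width_range[2],
             "peak widths must be positive")
  }
  structure(list(n_genes = as.integer(n_genes),
                 chrom_length = chrom_length,
                 gene_length_range = gene_length_range,
                 peak_sets = peak_sets, chrom = chrom,
                 seed = as.integer(seed)),
            class = "interval_sim_config")
}

#' Simulate gene models and peak interval layouts
#'
#' Genes are placed without overlap on one synthetic chromosome (an interior
#' margin keeps every enhancer band on-chromosome). Peaks are placed per
#' policy: `promoter` peaks have their midpoint within ±3 kb of a TSS;
#' `enhancer_band` peaks lie entirely within 3-125 kb of a TSS, avoid every
#' promoter window, and overlap a co-generated H3K27ac peak; `random` peaks
#' are uniform.
#'
#' @param cfg an [interval_sim_config()].
#' @return list with `genes` (gene model data.frame `gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and `peaks` (named list of interval
#'   data.frames; enhancer-band sets gain a companion `<name>_h3k27ac` set).
#' @export
simulate_intervals <- function(cfg) {
  .stop_if(!inherits(cfg, "interval_sim_config"),
           "'cfg' must come from interval_sim_config()")
  .with_seed(cfg$seed, {
    margin <- 130000
    usable <- cfg$chrom_length - 2 * margin
    slot <- floor(usable / cfg$n_genes)
    len <- round(runif(cfg$n_genes, cfg$gene_length_range[1],
                       cfg$gene_length_range[2]))
    .stop_if(any(len >= slot),
             "generation error: gene lengths do not fit the chromosome")
    start <- margin + (seq_len(cfg$n_genes) - 1L) * slot +
      floor(runif(cfg$n_genes, 0, slot - len))
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
                        chrom = cfg$chrom, start = start, end = start + len,
                        strand = sample(c("+", "-"), cfg$n_genes,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    tss <- gene_tss(genes)
    prom_win <- .tss_windows(genes, 3000)
    peaks <- list()
    for (nm in names(cfg$peak_sets)) {
      ps <- cfg$peak_sets[[nm]]
      np <- ps$n_peaks
      w <- round(runif(np, ps$width_range[1], ps$width_range[2]))
      if (ps$placement == "random") {
        s <- floor(runif(np, 0, cfg$chrom_length - w))
        peaks[[nm]] <- .peak_df(cfg$chrom, s, s + w, nm)
      } else if (ps$placement == "promoter") {
        g <- sample.int(cfg$n_genes, np, replace = TRUE)
        mid <- tss[g] + round(runif(np, -3000, 3000))
        s <- pmax(0, mid - floor(w / 2))
        peaks[[nm]] <- .peak_df(cfg$chrom, s, s + w, nm)
      } else { # enhancer_band
        s <- integer(np); e <- integer(np)
        ac_s <- integer(np); ac_e <- integer(np)
        for (i in seq_len(np)) {
          ok <- FALSE
          for (try in seq_len(1000L)) {
            g <- sample.int(cfg$n_genes, 1L)
            side <- sample(c(-1L, 1L), 1L)
            lo <- if (side > 0) tss[g] + 3000 else tss[g] - 125000
            hi <- if (side > 0) tss[g] + 125000 else tss[g] - 3000
            if (hi - lo < w[i]) next
            si <- floor(runif(1, lo, hi - w[i]))
            cand <- data.frame(chrom = cfg$chrom, start = si,
                               end = si + w[i])
            if (any(interval_overlaps(cand, prom_win))) next
            s[i] <- si; e[i] <- si + w[i]
            acw <- round(runif(1, ps$width_range[1], ps$width_range[2]))
            ac_s[i] <- max(lo, si - floor(acw / 3))
            ac_e[i] <- min(hi, ac_s[i] + acw)
            if (ac_e[i] <= s[i] || ac_s[i] >= e[i]) { ac_s[i] <- si
              ac_e[i] <- si + max(1L, floor(w[i] / 2)) }
            ok <- TRUE
            break
          }
          .stop_if(!ok, "generation error: could not place enhancer-band ",
                   "peak; chromosome too crowded")
        }
        peaks[[nm]] <- .peak_df(cfg$chrom, s, e, nm)
        peaks[[paste0(nm, "_h3k27ac")]] <-
          .peak_df(cfg$chrom, ac_s, ac_e, paste0(nm, "_h3k27ac"))
      }
    }
    list(genes = genes, peaks = peaks)
  })
}

.peak_df <- function(chrom, start, end, set) {
  o <- order(start)
  data.frame(chrom = chrom, start = as.integer(start[o]),
             end = as.integer(end[o]),
             name = sprintf("%s_%04d", set, seq_along(start)),
             score = 0L, strand = ".", stringsAsFactors = FALSE)
}
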