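---
title: "Methods: allele-specific analysis of XCI maintenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific analysis of XCI maintenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcimaint)
```

## The problem and the model

In female mammalian cells one X chromosome (the Xi) is transcriptionally
silenced, and the silent state is actively maintained by continuous
expression of the long non-coding RNA *Xist*. In hybrid cells whose Xi and
Xa carry different strain haplotypes (here, a 129 Xi and a CAST Xa), RNA-seq
reads overlapping strain SNPs can be assigned to one allele, giving per-gene
counts `reads_xi` and `reads_xa`. The central statistic of this package is
the **d-score**,

$$ d = \frac{\mathrm{Reads_{Xi}}}{\mathrm{Reads_{Xi}} +
\mathrm{Reads_{Xa}}} - 0.5, $$

which ranges from $-0.5$ (fully Xa-monoallelic, i.e. complete Xi silencing)
to $+0.5$ (fully Xi-monoallelic), with 0 meaning biallelic balance. From
d-scores in two conditions (wild type and Xist-deleted; or scramble- and
YY1-knockdown) the package derives the classifications the analysis rests
on:

* **analyzable** — at least `min_allelic_reads` (default 10) allelically
  assigned reads in a condition; comparisons between conditions use only
  features analyzable in *both*;
* **XCI escape vs subjective** — escape iff
  $\mathrm{Reads_{Xi}} \ge 0.05 \cdot \mathrm{Reads_{Xa}}$ in wild type,
  boundary inclusive;
* **Xist-dependent vs independent** — dependent iff the mutant d-score
  exceeds the wild-type d-score by at least 0.03, boundary inclusive; the
  symmetric three-way variant (`increased` / `decreased` / `unchanged` at
  $\pm 0.03$) is used for allelic peak intensities and knockdown
  comparisons.

The headline inference is the association between the two classifications:
a 2×2 table of escape status by dependence, tested with a two-sided Fisher
exact test (probability-mass criterion, computed in log space). A
chi-squared variant (`chi_squared_2x2()`) is provided for category
comparisons with more than 300 units (`choose_test()`), and a two-sample
Kolmogorov–Smirnov test compares expression fold-change distributions of
X-linked versus autosomal genes.

## Numerical choices

**Ratio thresholds are applied exactly.** The escape rule compares integer
counts by cross-multiplication against the exact rational form of the
threshold (1/20 for the default 0.05), recovered by continued fractions.
This makes the inclusive boundary exact — `(xi = 5, xa = 100)` escapes —
and gives `xa = 0, xi > 0` a well-defined answer (escape) without dividing
by zero. The case is flagged in the output (`xa_zero_wt`) because an
unbounded ratio deserves the analyst's eye.

**d-score boundaries use a 1e-12 absolute guard.** d-scores are rationals
with denominators bounded by the read depth; for any two analyzable
features with depth at most ~1e5 the difference between a d-score shift
and the 0.03 threshold is either exactly zero or at least ~1e-12, far
above double-precision error on these magnitudes. The guard therefore
turns float comparison into the exact rational comparison; the test suite
verifies this against exact integer arithmetic for every count pair with
total ≤ 200.

**Fisher ties.** Two-sided Fisher p-values sum all hypergeometric masses
not exceeding the observed one; masses within a relative 1e-7 of the
observed count as ties and are included. This tie convention (shared by
the standard implementations) is treated as part of the statistic's
definition: the exhaustive oracle in the tests applies the same rule to
exact integer numerators.

**K-S p-values** are exact (enumeration over label assignments) when the
smaller sample has at most 10 observations, asymptotic otherwise; the
fold-change comparisons that motivate the test involve hundreds of genes,
where the asymptotic form is standard.

## The non-allelic expression arm

Bulk counts from populations without usable SNPs are handled without
allelic resolution. FPKM is computed as
$10^9 \cdot c / (\mathrm{total} \cdot \mathrm{length_{bp}})$; genes with
mean FPKM ≥ 1 are *active*. Size factors use the median-of-ratios
definition (geometric-mean pseudo-reference over genes positive in every
sample), implemented in-package so the DEG logic is self-contained; the
test suite cross-checks it against an independent implementation.

DEG calls are deliberately simple, matching the two-replicate design: an
active gene is up (down) when its normalized count is higher (lower) in
the perturbed genotype in **both** replicate comparisons. Three decisions
here were genuinely open and are resolved as follows:

* *Which genotype must be active?* The activity filter accepts a gene
  active in at least one genotype (`active_scope = "any"`), so both
  induced and silenced genes are assessable; `"both"` and `"wt"` are
  available.
* *Replicate pairing.* Replicates are compared by index (WT rep 1 vs KO
  rep 1, rep 2 vs rep 2) — the weakest assumption consistent with the
  n = 2 design; an all-pairs mode is available and is strictly more
  conservative.
* *Ties.* Equal normalized counts are neither an increase nor a decrease;
  a tied comparison yields `non`.

DEGs shared with identical direction by all populations are common DEGs
(cDEGs); all other DEGs are lineage-specific (lsDEGs). Direction-discordant
sharing counts as lineage-specific. Signature genes for a three-population
comparison require significant upregulation (p < 0.05, FPKM ≥ 1) in the
focal population and FPKM < 1 in both others; because the underlying study
does not name its test, the default p-values come from a one-sided Welch
test on log2(FPKM + 1) of focal versus pooled-other replicates
(`signature_pvalues()`) — an approximation, and externally computed
p-values can be supplied instead.

## Peak conventions

All intervals are 0-based half-open (BED); overlap means at least 1 shared
bp, so abutting intervals do not overlap. Signal densities are RPKM
(region-level, depth-normalized) and RPK (peak-level, on
already-normalized counts). Consensus peaks are regions supported by at
least 50% of samples (inclusive); merged peak universes bridge gaps of up
to 1000 bp (the `merge -d 1000` convention, gap measured as
`next.start − prev.end`).

A peak is TSS-proximal when it overlaps the ±3 kb window around any TSS
(the window covers positions TSS ± 3000 inclusive), TSS-distal otherwise.
"Within ±3 kb of a TSS" is interpreted as *interval overlap with the
window* — consistent with the ≥ 1 bp overlap convention — while
nearest-TSS *annotation* distance uses the peak midpoint; the peak-to-TSS
measurement point (edge, midpoint or summit) is not fixed by the source
analysis, and the midpoint is the summit-free choice. Distal peaks are
annotated to the nearest gene body (distance 0 when overlapping, else the
half-open gap). Equidistant ties break to the lexicographically smallest
gene id and are flagged `ambiguous` — reproducibility over library order.
TSS is `start` for `+` genes and `end − 1` for `-` genes; unstranded gene
models are rejected rather than guessed.

YY1 peaks within ±3 kb of a TSS are promoter peaks; remaining peaks that
overlap an H3K27ac peak and lie within 3–125 kb of a TSS are enhancer
peaks (the 125 kb bound reflecting the typical promoter–enhancer
interaction distance); everything else is `other`. Promoter peaks annotate
to *all* genes within ±3 kb and enhancer peaks to all genes within
±125 kb, so one peak may annotate several genes. Promoter and enhancer
labels are disjoint because promoters are assigned first.

## What the synthetic-data generator emulates

The generators exist so that every stage is testable against known ground
truth without sequencing data.

`simulate_allelic_counts()` draws each gene's total allelic depth from a
negative-binomial law (mean `depth_mean`, default 1e4; dispersion 0.3,
degenerating to Poisson at 0) and Xi reads binomially from the gene's true
Xi fraction. Defaults mirror the observed wild-type regime: 352 genes, an
escape fraction of 18/352, dependence probability 14/18 for escape and
21/334 for subjective genes, subjective genes at Xi fraction 0.005 and
escape genes uniform on [0.05/1.05, 0.4] (the lower bound is the exact Xi
fraction at which the 5% ratio rule holds in expectation). Dependent genes
have their mutant Xi fraction raised by `dependent_shift` (default 0.1),
which raises the expected d-score by the same amount — comfortably above
the 0.03 call threshold, so recovery failures indicate implementation
defects rather than sampling noise. No generative model is prescribed by
the source analysis; these are pragmatic choices, fixed once.

`simulate_expression_matrix()` plants cDEGs (same direction everywhere)
and lsDEGs (one population each) on a log-normal baseline with
negative-binomial noise; planted DEGs receive a floor on their baseline
mean so the planted signal is detectable at the default depth.
`simulate_intervals()` lays non-overlapping genes on one synthetic
chromosome (an interior margin keeps enhancer bands on-chromosome) and
places peaks by policy — promoter midpoints within ±3 kb of a TSS;
enhancer-band peaks entirely within 3–125 kb, clear of every promoter
window, and overlapping a co-generated H3K27ac peak — so each annotation
rule has fixtures that exercise it by construction.

Each generator seeds its own RNG from the config and restores the caller's
RNG state, so identical configurations are byte-identical regardless of
call order.

**What passing tests do not show.** The simulators draw counts from clean
parametric laws: no mapping bias between alleles, no SNP-density variation
in allelic assignability, no correlated noise between replicates, no
peak-calling artifacts. Recovery rates near 100% on synthetic data
validate the *logic* of the rules, not their power on real libraries,
where allelic depths are far more skewed than a single negative-binomial
mean suggests (per-gene allelic depth distributions were not reported and
the defaults are not fitted).

## Problem sizes and reproducibility

The shipped test suite and the acceptance script use: an exhaustive d-score
grid over all count pairs with total ≤ 200; exhaustive Fisher comparison
against a rational-arithmetic oracle over every 2×2 table with total ≤ 40;
100 random interval fixtures of up to 150 intervals against quadratic
oracles; 1000-gene allelic simulations at depth 1e4; and 600-gene,
three-population expression simulations with 100-seed property sweeps on
smaller fixtures. These sizes give the property checks dense coverage
while keeping a full run to a couple of minutes on one core.

## Known limitations

* DEG calling is a sign-consistency rule, not a test with error control;
  with two replicates roughly half of all null genes are direction-
  consistent in any one population (the identities and the cDEG logic,
  not per-population DEG lists, are the meaningful output).
* The escape threshold applies to raw allelic counts; the ratio is
  invariant to equal scaling of both alleles, so library-size
  normalization does not affect it, but allele-specific mapping bias
  would.
* The Welch-test default for signature genes is a stand-in for an
  unspecified test; supply your own p-values where they exist.
* `fisher_exact_2x2()` is exact for any table, but the chi-squared
  variant inherits the usual asymptotic caveats at small expected counts;
  the `choose_test()` rule exists precisely to route small comparisons to
  the exact test.
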