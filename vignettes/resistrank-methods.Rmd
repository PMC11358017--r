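---
title: "Methods: rank-product meta-analysis and dose-response quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-product meta-analysis and dose-response quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistrank)
```

# The model and its assumptions

`resistrank` identifies genes consistently up-regulated in tumors that do
not respond to immune checkpoint blockade, by combining several small and
heterogeneous pretreatment cohorts at the level of fold-change *ranks*
rather than effect sizes. The core assumptions are:

* within each cohort, log2 expression is approximately Gaussian per gene,
  so a two-sample t-type statistic is appropriate;
* cohorts are independent, and under the global null a gene's fold-change
  rank is uniform on `1..n_i` independently across cohorts;
* consistency of *direction* across cohorts is the signal of interest —
  platform- and species-specific effect magnitudes are deliberately
  discarded by ranking.

Per cohort, `moderated_t()` computes the empirical-Bayes moderated t:
gene-wise pooled variances `s²_g` (residual df `d`) are shrunk toward a
prior, `s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)`, and `t = log2FC / (s̃_g
√(1/n₁+1/n₂))` is referred to a Student t with `d₀ + d` df. The prior is
estimated by matching the first two moments of `log s²_g` to a scaled-F
model (digamma/trigamma inversion of the excess dispersion). At `d₀ = 0`
this is exactly the classical pooled t; at `d₀ = ∞` all genes share
`s₀²`. The test suite cross-checks the whole path against an independent
reference implementation of the same shrinkage model to machine
precision, and a Welch alternative (`welch_t()`) is provided for
heteroscedastic cohorts.

`rank_by_lfc()` ranks by log2 fold change with rank 1 the most
up-regulated gene in non-responders (average ranks on ties), and
`rank_product()` combines cohorts by the relative geometric mean
`rho = (Π r_i/n_i)^(1/k)`. Relative ranks are the primary statistic so
cohorts with different gene universes combine coherently; the raw integer
product is reported alongside and is the statistic of the enumeration
oracle. Genes missing from some comparisons are retained when present in
at least `min_studies` of them (default: all), with a `k`-specific null.

Two significance routes are computed side by side, because both are
legitimate summaries of cross-study consistency and they answer slightly
different questions: the rank-product p-value (consistency of ranks) with
BH adjustment, and Fisher's one-sided combination of the per-study
upper-tail moderated-t p-values (consistency of evidence). The headline
ordering follows `rho`; neither p-value is promoted as "the" result.

# Rank-product p-values: exact, gamma, permutation

`rp_pvalue_exact()` counts, by a truncated-divisor recursion, the rank
tuples whose product does not exceed the observed one; it is exact but
limited to `Π n_i` up to an enumeration budget (default 1e7 — note this
covers two full 1,321-gene cohorts). `rp_pvalue_gamma()` is the
production method: in the continuous limit `-Σ log(r_i/n_i)` is
Gamma(k, 1), and the half-offset `(r_i - ½)/n_i` is the package's
discreteness correction (a midpoint rule on the rank lattice). For
`k = 1` the null tail is exactly `r/n`, so that value is returned and no
approximation is invoked. `rp_pvalue_permutation()` draws seeded uniform
rank tuples and reports `(1 + #[rho* ≤ rho])/(B + 1)` with its
Monte-Carlo standard error.

The accuracy of the gamma route depends on the universe size, and the
package is explicit about the regime it certifies. At cohort scale the
approximation is excellent: exhaustive comparison against the enumeration
oracle at `n = (1321, 1321)` shows absolute errors below 7e-4, and at the
four-cohort scale it agrees with `B = 1e5` permutation within Monte-Carlo
error (both are asserted in the test suite). On *very small* universes
(tens of genes or fewer) the discrete null is dominated by tie-class
jumps — at `n = (8, 8)` the single product value 8 carries probability
mass 4/64 — so no continuous approximation can track the exact
distribution closely there; absolute deviations of ~0.1 occur. This is a
structural property of the discrete statistic, not a tuning issue: when
universes are tiny, use `rp_pvalue_exact()` (enumeration is cheap exactly
when the approximation is poor), or the permutation route. The gamma
method is intended for the genomic regime it is used in by `run_meta()`.

Other numerical choices: tied (non-integer average) ranks route to the
gamma/permutation methods, since the enumeration oracle is defined on
integer ranks; one-tailed p-values of exactly 0 entering the Fisher
combination are floored at 1e-300 and flagged rather than erroring;
zero-variance genes are floored at the 1st percentile of positive gene
variances and flagged, keeping them in the rank universe with a finite t.
BH adjustment is delegated to `stats::p.adjust(method = "BH")` behind a
validating wrapper; Storey q-values are not offered.

The metabolic filter (`filter_and_rank_metabolic()`) is applied *after*
the statistics are computed on the full universe — the filtered table
keeps its p-values and only the final meta-rank is re-assigned. Whether
filtering should precede BH adjustment is genuinely ambiguous; both are
supported (`filter_before_bh`), with "after" as the default since the
filtered ranking is described as a restriction of the full meta-analysis
result. The metabolic list itself must be supplied by the user (GMT via
`read_gmt()`); the packaged demo list is a small synthetic placeholder,
as is the packaged pair of macrophage/CD8 demo signatures.

# What the synthetic generator emulates — and what it does not

`simulate_cohorts()` emulates the *shape* of a four-cohort ICB
responder/non-responder meta-analysis: a shared gene universe (default
10,000 genes of which 1,321 are flagged metabolic, mirroring the size of
a curated metabolic gene list), per-gene baseline levels shared across
cohorts, a per-study per-gene additive batch offset (`batch_sd`, default
0.5 log2 units) emulating platform/species heterogeneity, i.i.d. Gaussian
residual noise (default sd 1 log2 unit, a typical between-sample spread
for bulk RNA-seq log expression at moderate depth), and a spike table of
genes truly shifted in non-responders. Group sizes default to 10 vs 10
per cohort — the real cohorts' group sizes are not all published, so this
is a packaged choice of plausible magnitude, not an inference. Spiked
genes are always members of the simulated metabolic set, since the
recovery question is whether the pipeline finds them after filtering.

The model is Gaussian on the log2 scale. It does **not** simulate
read-level counts, library-size effects, single-cell sparsity, or the
empirical distributions of any real cohort, and the shared gene namespace
simulates away cross-species ortholog mapping (real use accepts a mapped
universe). Passing tests therefore certify the *statistical machinery* —
calibration under the null, power against consistent spikes, correctness
of the combination rules — not performance on any particular real
dataset.

Because the batch offset cancels between arms of the same study, the
noiseless configuration reproduces spiked fold changes exactly, which the
tests exploit as an oracle. Under the null the generator's p-values are
calibrated: a 10,000-gene, four-cohort null simulation keeps the
empirical CDF of both rank-product and Fisher p-values at or below the
uniform reference (within three binomial standard errors), and no gene
survives BH adjustment.

# Dose-response quantification

`peak_delta_ratio()` reduces a Fura-2 F340/F380 trace to the normalized
peak response: (post-stimulus maximum − pre-stimulus mean) divided by the
ionomycin amplitude of the same preparation, requiring at least five
pre-stimulus samples and a positive ionomycin response.

`fit_hill()` fits `baseline + Emax·c^h/(EC50^h + c^h)` by nonlinear least
squares (Levenberg–Marquardt via `minpack.lm`), with the EC50 optimized
as `log EC50` and multi-started over a 7-point log-spaced grid spanning
the observed concentration range extended one log unit either side; the
lowest-RSS candidate wins, and the optimizer contract (returned RSS ≤
every candidate RSS) is tested. Defaults: baseline fixed at 0 (responses
arrive baseline-subtracted from `peak_delta_ratio()`; free-baseline flag
provided), Hill coefficient free within [0.3, 4] — at eight
concentrations a completely unconstrained slope is weakly identified, and
a `fix_h = 1` flag is available for sparser designs. All replicate points
are fitted (option `on_means` mirrors the common fit-on-means practice).
Standard errors are asymptotic, from the Jacobian at the optimum, with
`SE(EC50) = EC50·SE(log EC50)` by the delta method. Fits with
`SE(EC50)/EC50 > 1` or vanishing Emax are flagged non-identifiable; EC50
estimates outside the sampled range extended one log unit are flagged
extrapolated. `compare_potency()` forms the EC50 ratio of two fits with a
CI by error propagation on the log scale.

The default synthetic concentration grid is eight half-log-spaced points
starting at 1 nM (up to ~3.16 µM), a conventional plate-assay design that
brackets nanomolar potencies; degenerate inputs (zero-concentration
baseline points) map to the lower asymptote. Unit invariance holds by
construction: rescaling concentrations rescales the EC50 linearly and
leaves `h` and `Emax` unchanged, which is property-tested.

# Immune-context statistics

Signature scores are per-sample means of gene-wise z-scores over the
signature genes present (constant genes contribute 0 via a variance
floor); this simple scheme is affine-invariant and sufficient for
median-split stratification — rank-based (ssGSEA-style) scoring is out of
scope. `dichotomize()` uses strict median inequalities on both scores, so
intermediate samples are excluded and strata can be unequal — the
structural reason a cohort can split, e.g., 64 vs 31. `compare_groups()`
is the unpaired two-tailed pooled-variance t-test.
`celltype_mean_correlation()` treats datasets as observations
(pairwise-complete, at least three datasets) for Pearson or Spearman
correlation of per-cell-type average expression. `dotplot_summary()`
min–max scales group means per gene to [0, 1] and reports the fraction of
samples expressing above a threshold (default 0); "standard scaled"
summaries of this kind are not uniquely defined, so the scaling and the
expressing threshold are both explicit, documented conventions.

# Problem sizes used by the tests and acceptance script

All simulations are seeded and desk-scale, chosen to keep the full suite
around a quarter of a minute while leaving comfortable statistical
margins: 200 fit repeats per agonist for EC50 recovery (median within
±25% of truth; observed medians sit within a few percent), 50 four-cohort
repeats for the spiked-gene power and adjusted-p checks, a single
10,000-gene four-cohort null for calibration, 5,000 genes for prior
recovery and null-uniformity KS checks, and `B = 1e5` for
permutation-oracle agreement.

# Known limitations

* The gamma p-value approximation should not be trusted on universes of
  tens of genes (use the exact or permutation route there; see above).
* Response-group labels are taken as given; deriving them (e.g. from
  tumor growth curves) is outside the package.
* No count-model differential expression, covariate adjustment, paired
  designs, precision weights, or random-effects meta-analysis.
* Ortholog mapping between species is accepted only as a user-supplied
  mapped universe.
* Kinetic modeling of calcium transients is not attempted; the Hill form
  is purely empirical, and the Hill coefficient reported at eight
  concentrations should be interpreted cautiously.
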