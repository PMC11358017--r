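# resistrank

Cross-cohort rank-product meta-analysis of immunotherapy-resistance genes,
with the downstream immune-context statistics and calcium dose–response
quantification that go with it.

## The problem

Pretreatment transcriptomes of tumors that respond or fail to respond to
immune checkpoint blockade (ICB) are available from several small,
heterogeneous cohorts — different species, platforms and group sizes — so
effect sizes cannot be pooled directly. A rank-based meta-analysis asks a
weaker, more robust question: which genes are *consistently* up-regulated
in non-responders across every cohort? Filtering the combined ranking to
metabolic genes then yields candidate metabolic drivers of ICB resistance
(the analysis that singled out cytidine deaminase, CDA). `resistrank` is
for computational biologists who want that pipeline as tested, reusable
functions rather than a one-off script.

## The statistics

For each cohort the package computes per-gene log2 fold changes
(non-responder minus responder) and empirical-Bayes moderated t-statistics:
gene variances are shrunk toward a prior, `s²_g → (d₀s₀² + d·s²_g)/(d₀+d)`,
with `(d₀, s₀²)` estimated by moment matching of `log s²_g` against a
scaled-F model (digamma/trigamma inversion). Genes are ranked by fold
change — rank 1 = most up-regulated in non-responders — and ranks are
combined across the `k` comparisons by the rank product

```
rho_g = ( Π_i r_{g,i} / n_i )^(1/k)
```

Small `rho_g` means consistent up-regulation. Its null distribution (under
independent uniform ranks) is computed three ways: exactly by enumeration,
by a Gamma(k, 1) upper tail at `T = −Σ log((r_i − ½)/n_i)`, or by seeded
permutation. Rank-product p-values are Benjamini–Hochberg adjusted; in
parallel, the per-study one-tailed moderated-t p-values are combined with
Fisher's method (`X = −2Σ log p_i ~ χ²_{2k}`). The result is filtered to a
metabolic gene set and re-ranked.

Companion modules cover signature-based cohort stratification
(macrophage^high/CD8^low versus the converse, by strict median splits),
per-cell-type mean-expression correlations across datasets, dot-plot
summary statistics, and Hill-equation fitting
`response = baseline + Emax·c^h/(EC50^h + c^h)` for ionomycin-normalized
Fura-2 calcium responses (multi-start nonlinear least squares, EC50 on the
log scale). A synthetic-data module generates multi-cohort expression data
and dose–response assays with known ground truth so every stage can be
exercised at desk scale.

## Worked example

```r
library(resistrank)

cfg <- sim_config(n_genes = 2000, n_studies = 4, n_responders = 10,
                  n_nonresponders = 10, spike = c(gene0042 = 2.5),
                  metabolic_fraction = 0.25, seed = 42)
sim  <- simulate_cohorts(cfg)
meta <- run_meta(sim$studies, metabolic = sim$metabolic_genes)
print(meta, n = 5)
#> Rank-product meta-analysis: 4 comparisons, 2000 genes (500 after metabolic filter)
#>   statistic: moderated t; p-values: gamma; filter after BH
#> Top genes:
#>  meta_rank     gene k     rho      p_rp     p_adj  p_fisher
#>          1 gene0042 4 0.00050 2.606e-11 5.211e-08 5.837e-31
#>          2 gene0567 4 0.05828 2.975e-03 8.891e-01 3.604e-03
#>          3 gene0549 4 0.06175 4.195e-03 8.891e-01 3.730e-03
#>          4 gene1330 4 0.08572 1.062e-02 9.382e-01 7.852e-03
#>          5 gene1338 4 0.09578 1.466e-02 9.382e-01 7.376e-03
```

The gene spiked at log2FC 2.5 in all four cohorts tops the metabolic
ranking with a BH-adjusted rank-product p of 5.2e-08 (it was ranked 1 in
every cohort, so `rho = 1/2000`); every null gene stays far from
significance on both p-value routes.

```r
fit <- fit_hill(simulate_dose_response(hill_params(42e-9, h = 1, emax = 0.8),
                                       seed = 42))
print(fit)
#> Hill concentration-response fit
#>   EC50 = 3.56e-08 M (35.6 nM), h = 0.816, Emax = 0.79, baseline = 0
#>   RSS = 0.06972 on 24 points; converged

fit2 <- fit_hill(simulate_dose_response(hill_params(103e-9, h = 1, emax = 0.8),
                                        seed = 43))
compare_potency(fit, fit2)
#> EC50 ratio (B/A): 2.548, 95% CI [1.600, 4.060]
```

One noisy 24-point assay recovers an EC50 of 35.6 nM from a true 42 nM,
and the potency ratio between two agonists generated at 42 versus 103 nM
is estimated at 2.55 with a CI well away from 1.

A thin command-line wrapper over the same functions ships in
`inst/scripts/resistrank` (subcommands `simulate`, `de`, `meta`,
`stratify`, `corr`, `fitdose`).

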