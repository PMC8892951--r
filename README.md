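# lbpnma

Network meta-analysis (NMA) of continuous trial outcomes, built for the
comparative-efficacy question in low back pain (LBP) pharmacotherapy:
many drug classes, mostly placebo-controlled two-arm trials, pain and
disability scores on heterogeneous scales. The package takes long-format
arm-level trial tables (tibbles in, tibbles out), builds standardized
mean differences, and estimates every pairwise treatment contrast in one
connected evidence network, with the full diagnostic battery an NMA
needs to be trusted.

## What it computes

* **Effect sizes** — Hedges' g with small-sample correction
  `J = 1 − 3/(4(n_t+n_c−2)−1)` and variance
  `v = (n_t+n_c)/(n_t n_c) + g²/(2(n_t+n_c))`; lower-is-better scales
  (pain, RMDQ, ODI) are sign-flipped so positive SMD always means benefit
  of the first treatment. Multi-arm trials become baseline-anchored
  contrast sets.
* **Pairwise meta-analysis** — DerSimonian–Laird random effects per
  direct comparison with Q, tau², I² and a chi-squared heterogeneity
  p-value.
* **Bayesian NMA** — the random-effects consistency model
  `y_i ~ N(δ_i, v_i)`, `δ_i ~ N(d_t1 − d_t2, τ²)` (multi-arm covariance
  τ²/2), reference effect fixed at 0, vague priors
  `d_k ~ N(0, 100²)`, `τ ~ U(0, 5)`. Fitted by an own
  Metropolis-within-Gibbs sampler (study effects integrated out
  analytically), 3 over-dispersed chains, split Gelman–Rubin
  diagnostics, league tables and `tidy()`/`glance()` summaries.
* **Ranking** — posterior rank probabilities and SUCRA on [0, 1].
* **Inconsistency** — global design-by-treatment interaction Wald test,
  loop-specific inconsistency factors with z-tests, and Bayesian
  node-splitting (direct vs indirect posterior with a two-sided Bayesian
  p-value).
* **Bias & sensitivity** — comparison-adjusted funnel points with an
  Egger-type intercept test, hat-matrix contribution matrices (per-column
  percentages summing to 100), leave-out refits against low-quality
  trials, and the GRADE "higher of direct and indirect" combiner.
* **Synthetic networks** — a generator with known truth (basic
  parameters, τ, designs, arm sizes, optional inconsistency offsets and
  small-study bias) plus a replication harness, so every stage has a
  parameter-recovery and calibration test bed.
* **LBP bookkeeping** — acute (≤ 12 weeks) / chronic (> 12 weeks) /
  radicular classification and the pain-outcome hierarchy
  (average > rest > walking > sleep).

## Worked example

```r
library(lbpnma)

trials <- simulate_network(sim_config(
  treatments = c("PLA", "SMR", "NSA", "OPI"),
  true_d = c(0, 0.3, 0.6, 0.9), tau = 0.1,
  n_trials_per_design = 15, n_per_arm = 50, seed = 42))

contrasts <- as_contrasts(trials)
build_network(trials, reference = "PLA")
#> <nma_network> 4 treatments (reference PLA), 6 edges, 90 study-contrast
#> pairs, 4 triangle(s); connected

fit <- fit_nma(contrasts, reference = "PLA",
               mcmc = nma_mcmc(n_iter = 5000, n_burnin = 2000, seed = 1))
tidy(fit)
#> # A tibble: 4 × 8
#>   term  treatment estimate  mean     sd ci_low ci_high  rhat
#>   <chr> <chr>        <dbl> <dbl>  <dbl>  <dbl>   <dbl> <dbl>
#> 1 d_NSA NSA          0.518 0.518 0.0445 0.429    0.605 1.000
#> 2 d_OPI OPI          0.853 0.853 0.0450 0.764    0.943 1.00
#> 3 d_SMR SMR          0.260 0.260 0.0440 0.174    0.347 1.00
#> 4 tau   <NA>         0.129 0.126 0.0397 0.0369   0.198 1.00

nma_ranking(fit)
#> # A tibble: 4 × 4
#>   treatment p_best sucra mean_rank
#>   <chr>      <dbl> <dbl>     <dbl>
#> 1 OPI            1 1             1
#> 2 NSA            0 0.667         2
#> 3 SMR            0 0.333         3
#> 4 PLA            0 0             4

design_by_treatment_test(contrasts, "PLA")
#> # A tibble: 1 × 6
#>    chi2    df p_value   tau2 estimable note
#>   <dbl> <int>   <dbl>  <dbl> <lgl>     <chr>
#> 1  1.01     3   0.799 0.0179 TRUE      <NA>
```

Reading the output: each posterior median is the SMD of that treatment
versus placebo (positive = more pain relief), with its 95% credible
interval and convergence diagnostic — here all three truths (0.3, 0.6,
0.9) sit inside their intervals and the between-study SD τ is recovered
near its true 0.1. OPI ranks first with SUCRA 1.0; the
design-by-treatment test finds no inconsistency in this (consistent by
construction) network, p = 0.80. `league_table(fit)` gives every pairwise
contrast, `autoplot(fit)` the forest plot, and
`inconsistency_report()` / `comparison_adjusted_funnel()` /
`contribution_matrix()` / `sensitivity_refit()` the diagnostics.

A YAML config can drive the same workflow end to end:
`run_simulate()`, `run_fit()`, `run_check()`, `run_sensitivity()` write
CSV/JSON artifacts and a run manifest to an output directory.

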