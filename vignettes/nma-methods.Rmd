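---
title: "Methods: Bayesian network meta-analysis of continuous pain outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network meta-analysis of continuous pain outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbpnma)
```

## The problem

Randomized trials of pharmacotherapy for low back pain (LBP) compare many
different drug classes — placebo, NSAIDs, opioids, skeletal muscle
relaxants, GABA-mimetic antiepileptics, combinations — but most trials
compare only two or three of them. A network meta-analysis (NMA) joins all
of these trials into one connected evidence network and estimates every
pairwise contrast simultaneously, borrowing strength through indirect
comparisons: if both drug A and drug B have been compared with placebo,
the A-vs-B effect is informed even when no head-to-head trial exists.
`lbpnma` implements this pipeline for continuous outcomes (pain-intensity
and disability scores), together with the diagnostics that make an NMA
credible: heterogeneity statistics, three kinds of inconsistency
assessment, small-study-effect regression, evidence-flow decomposition and
sensitivity refits.

## Data model and classification rules

Input is one row per study arm: `study_id`, `treatment`, `n`, `mean`,
`sd`, `outcome`, `direction`, `duration_weeks`, `radicular`, `rob`.
Treatments are opaque string codes in the field's abbreviation style
(`PLA`, `SMR`, `NSA`, ..., with `+` reserved for combinations such as
`NSA+GMA`). Two rules encode the clinical structure of LBP evidence:

* **Classification.** Radicular involvement (nerve-root pain) dominates:
  any radicular study is `radicular` regardless of duration; otherwise
  pain lasting at most 12 weeks is `acute` (subsuming subacute) and
  anything longer `chronic`. A non-radicular study without a duration is
  unclassifiable and rejected rather than guessed.
* **Outcome selection.** When a trial reports several pain conditions one
  is chosen by the fixed hierarchy *average pain intensity* > *pain on
  rest* > *pain on walking* > *pain on sleep*; functional outcomes are
  RMDQ (preferred) and ODI. When a study reports several time points the
  caller supplies the last one only; the package does not arbitrate time
  points.

## Effect sizes

Arm summaries become standardized mean differences using Hedges' g:
$d = (m_t - m_c)/s_p$, $g = J\,d$ with $J = 1 - 3/(4(n_t+n_c-2)-1)$ and

$$v = \frac{n_t + n_c}{n_t n_c} + \frac{g^2}{2(n_t+n_c)}.$$

The bias-corrected g (rather than Cohen's d) is the conventional default
for trial networks with many small studies. A deliberate sign convention
runs through the whole package: **positive SMD = benefit of the first
treatment**. Pain and disability scales are lower-is-better, so their mean
differences are sign-flipped at ingestion; this matches the field's
reporting style in which, e.g., SMD 0.58 for a muscle relaxant against
placebo means pain relief. A k-arm study is decomposed into k−1 contrasts
against one baseline arm (placebo when present, otherwise the first
treatment in a configurable order), all tagged with the study id so the
likelihood can restore their correlation.

## Pairwise stage

Each direct comparison is pooled by DerSimonian–Laird random effects:
fixed-effect weights $w_i = 1/v_i$ give Cochran's $Q$, the moment
estimator $\hat\tau^2 = \max(0, (Q-(k-1))/C)$ with
$C = \sum w_i - \sum w_i^2/\sum w_i$, random-effects weights
$1/(v_i+\hat\tau^2)$, a normal 95% CI and
$I^2 = \max(0,(Q-(k-1))/Q)$. With one study (or $Q=0$) heterogeneity is
reported as 0 with `het_defined = FALSE` instead of `NaN`. REML-style
alternatives were considered and not adopted: DL is the de facto standard
of this literature and is exactly reproducible by hand, which the test
suite exploits.

## The Bayesian consistency model

The core engine is the contrast-level random-effects consistency model

$$y_i \sim N(\delta_i, v_i), \qquad
  \delta_i \sim N(d_{t_1(i)} - d_{t_2(i)}, \tau^2),$$

with $d_{\text{ref}} = 0$. Contrasts from one multi-arm study share a
joint normal random effect with covariance $\tau^2/2$ off the diagonal —
the standard homogeneous-variance treatment that keeps a multi-arm trial
internally consistent by construction. Priors are vague in the style of
the NICE technical support documents and configurable:
$d_k \sim N(0, 100^2)$ and $\tau \sim U(0, 5)$, both far wider than any
plausible standardized effect.

**Sampler.** The study effects $\delta$ are linear-Gaussian and are
integrated out analytically, so each sweep is (i) an exact conjugate
multivariate-normal Gibbs draw of the basic parameters from
$y \sim N(Xd,\, V + \tau^2\Sigma_0)$ and (ii) a random-walk Metropolis
step on $\tau$ against the same marginal likelihood, reflected at zero,
with the step size adapted toward 44% acceptance during burn-in only (so
the post-burn-in chain is a fixed Markov kernel). This partial collapsing
matters: the naive scheme that samples $\delta$ explicitly couples
$\delta$ and $\tau$ and mixes so slowly that $\widehat R$ for $\tau$ stays
above 1.1 at moderate chain lengths, while the collapsed sampler reaches
$\widehat R \approx 1.00$ within a few thousand iterations.

Defaults: 3 chains, 20,000 post-burn-in iterations, 10,000 burn-in, thin
1. Chains start over-dispersed (diffuse basic parameters scaled by chain
index, $\tau$ spread across the prior range) from per-chain seeds derived
deterministically from the master seed. Convergence is declared when every
split Gelman–Rubin statistic is below 1.05; a failed check returns the fit
with `converged = FALSE` and a warning, never silently. Point estimates
are posterior medians (means also emitted).

## Ranking

Per MCMC draw, treatments (including the reference) are ranked by sampled
effect, rank 1 best. SUCRA is the surface under the cumulative ranking
curve, $\mathrm{SUCRA}_k = \sum_{r=1}^{K-1} P(\text{rank}_k \le r)/(K-1)$,
reported on [0, 1]; the scores always average 0.5. Exact within-draw ties
have probability zero for continuous posteriors, but a pinned rule exists
anyway: ties are broken by an internal fixed-seed generator, so reruns are
bit-reproducible and the caller's RNG stream is untouched.

## Inconsistency assessments

Three complementary views, mirroring how trial networks are audited:

* **Global (design-by-treatment interaction).** The consistency model and
  the saturated design-by-treatment model (one free mean per
  design-comparison combination) are both fitted by weighted least
  squares; the drop in weighted residual sum of squares is a Wald
  chi-squared statistic with df = rank difference. A single shared
  $\tau^2$ enters the weights, estimated by the method of moments *under
  the consistency model*: its larger residual df gives a visibly less
  noisy plug-in than the interaction-model variant, and in 1000-replicate
  calibration runs holds the test at size 0.04–0.06 where the noisier
  plug-in drifts anticonservative. Networks with no loop and no repeated
  design have df = 0 and are flagged `estimable = FALSE` — a degenerate
  result, not an error. Multi-arm studies contribute one design and can
  never witness inconsistency against themselves.
* **Local (loop-specific).** For each triangle, per-edge direct estimates
  are pooled with a loop-common moments $\tau^2$, and the inconsistency
  factor $IF = |\hat d_{AB} - \hat d_{AC} + \hat d_{BC}|$ is z-tested,
  with the 95% CI truncated below at zero (an absolute quantity). Loops
  are traversal-direction invariant. Only triangles are enumerated by
  default; quadrilaterals add little identifiable information in networks
  dominated by placebo-anchored designs.
* **Node-splitting.** The Bayesian model is refitted with a separate free
  parameter for the direct evidence on one comparison, while the rest of
  the network identifies the indirect estimate through the consistency
  structure (same priors). The report is the posterior of
  $\omega = d_{\text{dir}} - d_{\text{ind}}$ with
  $p = 2\min(P(\omega>0), P(\omega<0))$. A comparison whose removal
  leaves no indirect path is reported "not splittable". In multi-arm
  studies only contrasts whose treatment pair equals the split edge move
  to the direct parameter; their siblings stay in the consistency
  structure and keep the within-study correlation.

## Publication bias, evidence flow, sensitivity, grading

* **Comparison-adjusted funnel.** Every study effect is centered on its
  own comparison's random-effects pooled estimate, so all comparisons
  share one funnel; an Egger-type regression of $x/se$ on $1/se$ tests
  asymmetry through its intercept. The test needs SE variation across
  trials (otherwise the regressor is collinear with the intercept) and a
  coherent orientation: in a closed loop the off-reference comparison
  reverses sign under canonical orientation, so a bias that inflates
  active-vs-placebo effects partially cancels there — the power analyses
  therefore use placebo-anchored (star) networks.
* **Contribution matrix.** The aggregate weighted-least-squares hat
  matrix of the network estimator gives, for each network estimate, a
  unit evidence flow over the direct comparisons. That flow is decomposed
  into paths (shortest first), each path's flow shared equally among its
  edges; summed per edge and scaled to percentages, every column sums to
  100. The plain normalized-|h| shortcut was rejected because it
  misattributes indirect flow: in the equal-variance triangle it reports
  a 50% own-edge share where the flow decomposition gives the correct
  two-thirds direct / one-third indirect split. The whole-network
  variant (average contribution across estimates) is attached as an
  attribute; the per-estimate matrix is primary.
* **Sensitivity.** `sensitivity_refit()` re-runs the NMA without flagged
  studies (default: high risk-of-bias ratings) at matched seeds and
  reports per-comparison shifts in the posterior median plus any
  credible-interval conclusion changes (interval excluding 0 vs not).
* **GRADE.** Domain judgments are inputs, not computed. Only the
  combination rule is implemented: the NMA estimate inherits the
  *higher* of the direct and indirect ratings on
  very-low < low < moderate < high, with single-source pass-through.

## The synthetic generator

`simulate_network()` emulates the study conditions the pipeline is
designed for: a connected network of two- and multi-arm trials with known
basic parameters on the SMD scale, between-study SD $\tau$ with the same
$\tau^2/2$ multi-arm covariance the likelihood assumes, normal arm-level
outcomes summarized to (mean, sd, n), and optional perturbations — a fixed
SMD offset on one design's contrast (loop inconsistency) or effects
inflated proportional to the trial SE (small-study bias). Defaults are one
realistic configuration, chosen once: $\tau = 0.1$ (moderate heterogeneity
on the SMD scale), 15 trials per pairwise design, 50 participants per arm,
unit raw-scale SD, placebo-anchored baselines. `n_range` draws per-trial
arm sizes uniformly (e.g. 10–200) where SE variation matters. Arm-level
generation exercises the effect-size module end-to-end;
`simulate_contrasts()` is a shortcut for calibration loops.
`replicate_study()` fans out replicate seeds as
`seed + r * 10^6` and records callback failures per replicate.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: non-normal outcomes, missing or imputed SDs,
dropout, scale heterogeneity between instruments beyond what
standardization absorbs, correlated multiple outcomes, and selective
reporting beyond the simple SE-proportional inflation model.

## Numerical choices and degenerate inputs

* $I^2$ and $\tau^2$ report 0 (flagged) at $k=1$ or $Q=0$; the DL
  truncation at zero is exact.
* $\widehat R$ on constant chains returns `NA` with a degeneracy flag.
* The flow decomposition stops at a $10^{-9}$ residual; columns sum to
  100 within 0.1.
* League tables are antisymmetric by construction since every entry is
  computed from the same draws.
* Problem sizes used by the test-suite simulations (chosen as the
  package's own desk-scale evaluation conditions): coverage is assessed
  over 100 replicates of a 3-treatment, 4-trials-per-edge network at 2
  chains x 1200 iterations; design-by-treatment calibration over 200
  replicates at 6 trials per design; node-split calibration over 30
  replicates. The flagship recovery run is the 4-treatment network with
  $d = (0, 0.3, 0.6, 0.9)$, $\tau = 0.1$, 15 trials per edge.

## Known limitations

Binary/rate outcomes, network meta-regression on covariates, P-scores,
trim-and-fill/selection models and automated GRADE downgrading are out of
scope. The contrast-level likelihood treats sampling errors of contrasts
sharing a control arm as independent (correlation enters only through the
random effects); this is the common aggregate-data approximation. Priors
are stand-ins for any specific published analysis's settings and should be
varied in sensitivity analyses when the between-study SD is weakly
identified (few studies per edge).
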