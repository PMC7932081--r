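---
title: "Estimating adolescent family planning indicators: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adolescent family planning indicators: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adolfp)
```

## The estimation problem

Survey evidence on contraceptive use among women aged 15–19 is sparse
and uneven. A country may contribute anywhere from zero to more than
five surveys; sources (DHS, MICS, RHS, WFS, PMA, national and other
programmes) differ in quality; some surveys sample non-baseline
populations (only ages 18+, or a geographic subset), and some
misclassify modern versus traditional methods. Married and unmarried
adolescents differ so much — in exposure, need, and reporting — that
they must be estimated separately and recombined. This package
implements a Bayesian hierarchical time-series model for that setting,
together with a synthetic-data generator rich enough to exercise every
part of the pipeline.

## Model

### Process model

For each country and marital group we model three quantities on an
annual grid (default 1970–2030):

1. **Total prevalence** `p(t)`: a logistic transition
   `p_sys(t) = a / (1 + exp(-r (t - m)))` with free asymptote
   `a ∈ (0, 1]`, rate `r > 0` per year, and midpoint year `m`. The free
   asymptote matters: many countries plausibly never approach universal
   use among 15–19-year-olds, and some stay at low prevalence
   throughout, using only the early portion of the curve.
2. **Modern share of use** `s(t)`: a second logistic transition with
   its own `(a, r, m)`.
3. **Unmet need among non-users** `u(t) = logit⁻¹(β₀c + β₁ p(t))`,
   a function of prevalence rather than of time: as use becomes normal,
   awareness and demand rise among non-users; at high prevalence the
   *population* unmet share `z(p) = (1 - p) u(p)` turns over and falls,
   reaching zero at `p = 1`. The intercept `β₀c` is country-specific,
   the slope `β₁` world-level. The functional form is a design choice
   (the qualitative turning-point behaviour is the constraint); it sits
   behind `unmet_link()` and is swappable.

Year-to-year variation and out-of-sample projection come from
stationary AR(1) deviations `δ(t)` added to `logit p_sys` and
`logit s_sys`. Throughout the package `ar_sd` is the **innovation**
standard deviation; the stationary variance is `ar_sd² / (1 - ρ²)`.
Unmet need carries no deviation of its own: it inherits variation
through the link, plus observation error — the minimal structure
consistent with three modelled quantities.

The four-way composition is assembled as
`modern = p·s`, `traditional = p·(1-s)`, `unmet = (1-p)·u`,
`no_need = (1-p)·(1-u)`; closure (sum = 1 within 1e-9) is enforced by
construction and asserted by tests on every emitted composition.

### Observation model

A survey record contributes up to three transformed data points:
`logit(p̂)`, `logit(p̂_modern / p̂)` and `logit(p̂_unmet / (1 - p̂))`.
Each is normal around the bias-adjusted latent value with variance

> delta-method sampling variance (from the recorded standard error,
> or a source-type default when absent) + non-sampling variance of the
> source type.

Non-baseline flags (`age_truncated`, `geographic_subset`,
`other_nonbaseline`) add estimated shifts on `logit p` and `logit u`;
an additive logit shift is a multiplicative odds effect, our reading of
"multiplier" bias parameters. Misclassification flags reallocate a
fraction of the donor method share (e.g. `modern_inflated` with
fraction γ turns `(modern, trad)` into `(modern + γ·trad,
(1-γ)·trad)`), never changing any-method use — a property tested
exhaustively. Bias shifts and reallocation fractions get zero-centred
normal priors (reallocations on the logit scale, so the prior centres
at one half) and are sampled jointly with everything else; the
source-type non-sampling sds are fixed configuration, because nothing
in a small panel identifies seven error variances.

Observed proportions of exactly 0 or 1 are moved to `1/(2n)` with
`n = 1000` by default — the standard continuity correction; the source
material is silent here.

Unmet-need observations for unmarried women refer to *all* unmarried
adolescents (not the sexually active subset); no re-basing is done.

### Hierarchy

Country parameters are shrunk through normal child-given-parent terms
on unconstrained scales (logit for asymptotes, log for rates, identity
for midpoints and the unmet intercept): world → region → subregion →
country for married women. For unmarried women, subregions are first
clustered into two sexual-activity groups (group 0: at most 2% —
inclusive — of unmarried women of reproductive age report sexual
activity in the past 28 days), giving world → group → region →
subregion → country with geography kept intact inside each group.
Level standard deviations get half-normal hyperpriors. Countries with
no data are still sampled and receive their subregion's predictive
distribution — that is the point of the hierarchy.

Root priors (chosen once; defaults in `default_hierarchy_priors()`):
asymptote logits centred at 0 (sd 1) for any-method use and at
logit(0.8) for the modern share; log-rates centred at log(0.08)/yr
(transitions spanning decades); midpoints at 2005/2000 with sd 20
years; unmet intercept at logit(0.15).

## Inference

`fit()` runs an adaptive Metropolis-within-Gibbs sampler, one marital
group at a time:

- **Marginalised AR(1).** Given curve parameters, the transformed
  observations of one country/component are jointly normal with
  covariance `ar_sd²/(1-ρ²) · ρ^|tᵢ-tⱼ| + diag(vᵢ)`. We work with that
  marginal likelihood (small Cholesky factorisations, cached until the
  AR parameters move; the kernel is compiled C++) instead of sampling
  61 deviations per country as latent states. The unmet-need terms use
  the systematic prevalence in the link — the one approximation in the
  likelihood; it is second-order in `ar_sd` and the calibration study
  (below) shows no measurable miscalibration at realistic noise.
- **Blocks.** Per-country 7-parameter Metropolis blocks; conjugate
  Gibbs for all hierarchy node means; Metropolis on log level-sds;
  one joint block for (slope, ρ_any, ρ_ratio, sd_any, sd_ratio); one
  joint block for the bias/misclassification parameters when flagged
  observations exist.
- **Adaptation.** Scalar step scales follow a Robbins–Monro recursion
  towards 23.4% acceptance; country and global blocks additionally
  learn full proposal covariances (Haario-style) with the accumulators
  restarted at mid-warmup and a 10% diagonal safeguard component. All
  adaptation freezes at the end of warmup.
- **Translation move.** A Metropolis move shifts one parameter's whole
  stack (world mean, node means, all country values) by a common
  amount; shrinkage residuals are invariant, so only the root prior
  and the likelihood enter. Without it the hierarchy's location mixes
  by a funnel-slow random walk — a prior-only run of 40,000 iterations
  still showed a world-mean sd of 0.78 against the true 1.0; with the
  move, prior-only runs reproduce the hyperprior and this is a frozen
  regression test.
- **Initialisation** is deterministic: hyperparameters at prior
  medians, country parameters at their hierarchy means, deviations at
  zero. Identical inputs and seed give bit-identical draws; every
  random stream derives from the single `seed`.
- **Trajectories.** For each retained draw, deviations on the
  estimation grid are drawn exactly by forward-filtering
  backward-sampling (vectorised across draws), and `project()`
  continues them beyond the last data year by sequentially sampling
  the AR(1) conditionals with that draw's own (ρ, sd) — the systematic
  parameters are time-invariant, so the curves extend directly.

The default run (4 chains × 10,000 iterations, 5,000 warmup, thin 5)
is desk-scale for panels up to ~30 countries. `model_config(fixed=)`
freezes any named parameter — that is how the test suite pins all but
one parameter and compares the sampler against a brute-force grid
posterior (total variation < 0.05 on a 50-cell partition of a
2,000-point grid).

### Known limitations of the sampler

Logistic-curve parameters are weakly identified when a country's data
do not reach the plateau: the asymptote trades off against midpoint
and rate, and those posteriors mix slowly. At the acceptance budget
(4×10,000 iterations, 20 countries) some scalars show R-hat up to
~1.7 and small effective sample sizes even though the substantive
acceptance checks (asymptote coverage ≥ 80%, midpoint MAE, predictive
calibration) pass. `diagnostics()` reports this honestly; production
runs on larger panels should use longer chains. R-hat here is the
classic potential scale reduction over whole chains (clamped at 1), so
that copied chains give exactly 1.

## Indicators

All-women draws are `w·married + (1-w)·unmarried` per draw, country
and year, with `w` the proportion married. Counts multiply proportions
by the group population (`w·pop` married, `(1-w)·pop` unmarried).
Aggregates are draw-level count sums, so aggregate proportions are
count-weighted and additivity is exact by construction. SDG 3.7.1 is
`modern / (any + unmet)` per draw. Summaries are empirical medians and
2.5th/97.5th percentiles; afterwards the modern and traditional
medians are rescaled proportionally so they sum to the any-method
median (uncertainty intervals are never adjusted, and total need is
reported as the median of draw-level `any + unmet` without forcing the
need identity at the median). Suppression: countries with fewer than
two married any-method observations are flagged for individual
reporting but retained in aggregates; SDG-ratio records are flagged
when a group's median women-in-need falls below a configurable floor
(default 100,000 — the reporting reason is stated in the source
material, the threshold is not).

## Synthetic data: what it emulates, and what a green test means

`simulate_truth()` draws a world down the same hierarchy family the
model assumes (configurable level sds), gives unmarried group-0
subregions a strongly depressed any-method asymptote, declining
country marriage proportions along a logistic in time, and log-normal
population sizes with country-specific growth. `simulate_surveys()`
reproduces the survey-compilation pathology: zero-inflated Poisson
survey counts (some countries empty, some with more than five), a
DHS-dominated source mix, per-source error variances, missing method
splits and missing unmet-need measurements, non-baseline bias flags
and misclassification flags whose *true* effect sizes are the config
defaults the fit tries to recover.

It does **not** emulate: microdata or questionnaire effects,
under-reporting by unmarried adolescents (a real-world bias with no
survey-internal signal), correlated country shocks, or non-logistic
trend shapes. A green recovery/calibration suite therefore establishes
that the inference machinery is correct *under the stated model*, not
that the model is right for any particular real compilation.

Defaults that define the stated world: surveys_mean 4 (married),
zero-inflation 0.15, unmarried factor 0.6, ar ρ 0.8, innovation sd
0.1, unmet slope 2, sampling ses ~0.012–0.015, non-sampling sds
0.10–0.25 by source. These were chosen once, from the sparsity
narrative and orders of magnitude a demographer would call realistic,
and are not tuned against test outcomes.

## Numerical choices

- Proportions are clamped to `[1e-12, 1-1e-12]` before logits inside
  the likelihood; observed boundary proportions use `1/(2n)`.
- The method-sum consistency tolerance on input records is 0.005
  (published tables round to one decimal in percent).
- Decimal reference years: whole-number years in input files are read
  as calendar years and mapped to the fieldwork midpoint `year + 0.5`.
- Estimate CSVs print doubles with 17 significant digits, so the
  write/read round trip is bit-exact.
- Observation years are assigned to their floor grid year for the AR
  covariance; curve means use the exact decimal year.

## Visualization

Compositional maps use (any-method use, unmet need, no need) — modern
and traditional merged into "use". `ternary_coordinates()` is the
barycentric map (pure components at vertices, balance at the
centroid); `ternary_color()` blends the three primaries (green = use,
pink = unmet, blue = no need) in linear RGB with the composition as
weights, then gamma-encodes, so pure components return their primary
exactly and the blend is permutation-equivariant. Uncertainty is
deliberately not encoded in maps; fan plots (`trajectory_plot()`) show
the median, dashed 80% bounds when present, a 95% ribbon, and source
observations coloured by source type.
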