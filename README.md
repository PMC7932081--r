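# adolfp

Bayesian hierarchical estimation and projection of family planning
indicators — contraceptive prevalence (any and modern methods), unmet
need, and the share of need satisfied by modern methods (SDG indicator
3.7.1) — **among adolescent women aged 15–19**, separately for married
and unmarried women, on an annual 1970–2030 grid.

The package is written for demographers and global-health analysts who
need country, regional and global estimates from sparse, heterogeneous
survey compilations: most countries have only a handful of surveys,
some none at all, and individual surveys carry known defects
(non-baseline sampling frames such as ages 18+, and misclassification
between modern and traditional methods).

## The model

For each country `c` and marital group, three quantities are modelled:

- total prevalence `p(t)` — a logistic transition curve on the year
  scale, `p_sys(t) = a / (1 + exp(-r (t - m)))`, with country-specific
  asymptote `a ∈ (0,1]`, rate `r > 0` and midpoint `m`; countries that
  never leave low prevalence are represented by the early part of the
  curve;
- the modern share of use `s(t)` — a second logistic curve;
- unmet need among non-users `u(t) = logit⁻¹(β₀c + β₁ p(t))` — a
  monotone function of prevalence, not of time, so the population-level
  unmet share `(1-p)·u` first rises and then falls as use crowds out
  need.

Smoothing and projection come from stationary AR(1) deviations on
`logit p` and `logit s`. Survey observations enter on the logit scale
with delta-method sampling variance plus a source-type non-sampling
variance; flagged observations receive estimated additive bias shifts
(logit scale) and modern/traditional reallocation fractions that
preserve any-method use. Countries borrow strength through a normal
hierarchy — world → region → subregion → country for married women,
with subregions nested in two sexual-activity groups (≤ 2% of unmarried
women reporting activity in the past 28 days = group 0) for unmarried
women.

The four-way composition (modern, traditional, unmet, no-need) always
sums to one. All-women estimates are marriage-proportion-weighted sums
of the two groups *at the draw level*; regional and global aggregates
are draw-level count sums, so every reported interval is a proper joint
posterior summary.

Inference is adaptive Metropolis-within-Gibbs with the AR(1) process
marginalised analytically; annual trajectories are reconstructed by
forward-filter backward-sampling and projected to 2030 by sequential
sampling from the AR(1) conditionals.

## Worked example

```r
library(adolfp)

cfg   <- sim_config()                       # 12 synthetic countries
truth <- simulate_truth(cfg, seed = 7)
obs   <- simulate_surveys(truth, cfg, seed = 7)

smp <- fit(obs, truth$demography, truth$meta, model_config(),
           mcmc_config(n_chains = 2, n_iterations = 1500,
                       n_warmup = 700, thinning = 4, seed = 3),
           marital_group = "married")
print(smp)
#> fp_samples: married women; 12 countries; 400 draws from 2 chains;
#> years 1970 - 2030 (data through 2019)

rec <- summarize_draws(smp, years = 2019)
head(rec[rec$location == "AAA", c("indicator", "median", "ui_low", "ui_high")], 4)
#>               indicator    median     ui_low   ui_high
#> 1               use_any 0.3302437 0.18719562 0.5045947
#> 2            use_modern 0.1367271 0.07142738 0.2273391
#> 3       use_traditional 0.1935167 0.10352688 0.3145251
#> 4                 unmet 0.2406120 0.19624237 0.2786711
```

The rows are posterior medians with 95% uncertainty intervals for one
synthetic country in 2019: about 33% of its married adolescents use
some method (after the median-identity adjustment, `use_modern +
use_traditional` equals `use_any` exactly), 24% have unmet need.
Downstream: `combine_marital()` for all-women draws,
`counts_from_proportions()` + `aggregate_counts()` for regional counts,
`need_satisfied_modern()` for SDG 3.7.1, `suppression_filter()` for the
reporting rules, `coverage_report()` for out-of-sample validation, and
`ternary_color()` / `ternary_coordinates()` for compositional maps.

A synthetic fixture bundle on disk (observations, demography, metadata,
truth):

```sh
Rscript inst/scripts/simulate.R --config cfg.yaml --seed 7 --out fixture/
```

## Layout

- `R/core_io.R` — CSV readers/writers, dataset validation
- `R/synthetic_data.R` — generator for truth, surveys, demography
- `R/process_model.R` — logistic transitions, unmet link, AR(1),
  composition assembly
- `R/observation_model.R` — bias/misclassification and the survey
  likelihood
- `R/hierarchy.R` — shrinkage trees and the hierarchical prior
- `R/inference.R`, `src/loglik.cpp` — the sampler, trajectory
  reconstruction, projection
- `R/indicators.R` — all-women weighting, counts, aggregation,
  SDG 3.7.1, summaries, suppression
- `R/validation.R` — holdout splits and predictive coverage
- `R/visualization.R` — ternary coordinates/colours, fan plots
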