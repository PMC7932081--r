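# Sampler mechanics: reproducibility, prior-only sanity, projection,
# diagnostics. The heavier oracle/recovery/calibration experiments live
# in test-acceptance.R.

test_that("fit is bit-reproducible and validates its inputs", {
  fixt <- cached_small_fit()
  smp2 <- fit(fixt$obs, fixt$truth$demography, fixt$truth$meta,
              model_config(),
              mcmc_config(n_chains = 2, n_iterations = 800,
                          n_warmup = 400, thinning = 2, seed = 99),
              marital_group = "married")
  expect_identical(fixt$smp$params, smp2$params)
  expect_identical(fixt$smp$comp, smp2$comp)

  expect_error(fit(fixt$obs, fixt$truth$demography, fixt$truth$meta,
                   model_config(), mcmc_config()),
               "separately")
  expect_error(mcmc_config(n_iterations = 100, n_warmup = 200),
               "n_iterations")
  expect_error(fit(fixt$obs, fixt$truth$demography, fixt$truth$meta,
                   model_config(fixed = c(bogus = 1)), mcmc_config(),
                   marital_group = "married"),
               "unknown fixed")
})

test_that("every stored composition sums to one and respects bounds", {
  smp <- cached_small_fit()$smp
  sums <- apply(smp$comp, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(smp$comp >= 0 & smp$comp <= 1))
  expect_equal(length(smp$years), dim(smp$comp)[3])
})

test_that("prior-only fit reproduces the hyperprior (funnel-free)", {
  meta <- make_meta(c("AAA", "AAB"))
  demog <- make_demog(c("AAA", "AAB"))
  smp <- fit(empty_obs(), demog, meta, model_config(),
             mcmc_config(n_chains = 2, n_iterations = 6000,
                         n_warmup = 1000, thinning = 2, seed = 2),
             marital_group = "married")
  w <- smp$params[, "mu.world.la_any"]
  expect_lt(abs(mean(w)), 0.15)
  expect_lt(abs(sd(w) - 1), 0.15)
  m <- smp$params[, "mu.world.m_any"]
  expect_lt(abs(mean(m) - 2005), 3)
  expect_lt(abs(sd(m) - 20), 3)
  # level sd recovers its half-normal prior median
  s <- smp$params[, "sigma.country.la_any"]
  hn_med <- 0.4 * qnorm(0.75)
  expect_lt(abs(median(s) - hn_med), 0.08)
})

test_that("projection continues the AR process correctly", {
  meta <- make_meta(c("AAA", "AAB"))
  demog <- make_demog(c("AAA", "AAB"))
  # noise-free error process: projection equals the systematic curve
  fx0 <- c(rho_any = 0.8, sd_any = 0, rho_ratio = 0.8, sd_ratio = 0)
  smp0 <- fit(empty_obs(), demog, meta, model_config(fixed = fx0),
              mcmc_config(n_chains = 2, n_iterations = 600,
                          n_warmup = 300, thinning = 2, seed = 4),
              marital_group = "married")
  j2030 <- which(smp0$years == 2030)
  for (d in c(1, 50)) {
    th <- smp0$params[d, ]
    sysv <- plogis(th[["theta.AAA.la_any"]]) /
      (1 + exp(-exp(th[["theta.AAA.lr_any"]]) *
                 (2030 - th[["theta.AAA.m_any"]])))
    p_any <- smp0$comp[d, "AAA", j2030, 1] + smp0$comp[d, "AAA", j2030, 2]
    expect_equal(p_any, sysv, tolerance = 1e-6)
  }

  # forecast variance law: var(dev_{T+k} - rho^k dev_T) over draws
  fx <- c(rho_any = 0.8, sd_any = 0.1, rho_ratio = 0.5, sd_ratio = 0.05)
  smp <- fit(empty_obs(), demog, meta, model_config(fixed = fx),
             mcmc_config(n_chains = 2, n_iterations = 2500,
                         n_warmup = 500, thinning = 1, seed = 4),
             marital_group = "married")
  yrs <- as.numeric(dimnames(smp$dev)[[3]])
  iT <- which(yrs == smp$est_end)
  for (k in c(1, 5, 20)) {
    dk <- smp$dev[, 1, iT + k, 1] - 0.8^k * smp$dev[, 1, iT, 1]
    expect_equal(var(dk), 0.1^2 * (1 - 0.8^(2 * k)) / (1 - 0.8^2),
                 tolerance = 0.15)
  }

  expect_error(project(smp, smp$est_end - 5), "precedes")
  expect_error(project(smp, 2100), "grid")
})

test_that("diagnostics compute R-hat and effective sample size", {
  smp <- cached_small_fit()$smp
  dg <- diagnostics(smp)
  expect_true(all(c("param", "rhat", "ess", "flagged") %in% names(dg)))
  expect_true(all(dg$rhat >= 1))

  # identical chains copied -> R-hat exactly 1
  set.seed(1)
  x <- rnorm(500)
  expect_equal(adolfp:::rhat_chains(cbind(x, x)), 1)
  # disjoint supports -> far above the flag threshold
  expect_gt(adolfp:::rhat_chains(cbind(rnorm(500), rnorm(500) + 50)), 5)
  # i.i.d. draws: ESS within 20% of the nominal draw count
  set.seed(2)
  mat <- matrix(rnorm(8000), 2000, 4)
  expect_lt(abs(adolfp:::ess_chains(mat) / 8000 - 1), 0.2)

  smp1 <- smp; smp1$n_chains <- 1
  expect_error(diagnostics(smp1), "2 chains")
})

test_that("countries without data are sampled from the hierarchy", {
  fixt <- cached_small_fit()
  obs1 <- fixt$obs[fixt$obs$marital_group == "married" &
                     fixt$obs$country_code != "AAA", ]
  smp <- fit(obs1, fixt$truth$demography, fixt$truth$meta,
             model_config(),
             mcmc_config(n_chains = 2, n_iterations = 800,
                         n_warmup = 400, thinning = 2, seed = 12),
             marital_group = "married")
  # the data-free country still has draws, with wider uncertainty than
  # a data-rich one
  j <- which(smp$years == 2010)
  p_free <- smp$comp[, "AAA", j, 1] + smp$comp[, "AAA", j, 2]
  informed <- names(which.max(table(obs1$country_code)))
  p_data <- smp$comp[, informed, j, 1] + smp$comp[, informed, j, 2]
  expect_gt(diff(quantile(p_free, c(0.025, 0.975))),
            diff(quantile(p_data, c(0.025, 0.975))))
})
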