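# Generator: determinism, noise-free limits, flag mechanics, fixtures.

test_that("sim_config validates its probabilities and size", {
  expect_error(sim_config(surveys_zero_inflation = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_regions = 1, n_subregions_per_region = 1,
                          n_countries_per_subregion = 1), "at least 2")
})

test_that("simulate_truth is deterministic and respects the noise-free limit", {
  cfg <- sim_config()
  expect_error(simulate_truth(cfg), "seed")
  t1 <- simulate_truth(cfg, seed = 3)
  t2 <- simulate_truth(cfg, seed = 3)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$demography, t2$demography)

  # AR sd = 0: latent trajectories equal the systematic curves exactly
  cfg0 <- sim_config(ar_sd = 0)
  tr <- simulate_truth(cfg0, seed = 5)
  code <- tr$meta$country_code[1]
  th <- tr$params$married[code, ]
  sys <- logistic_transition(cfg0$years, plogis(th[["la_any"]]),
                             exp(th[["lr_any"]]), th[["m_any"]])
  expect_equal(tr$trajectories$married[[code]]$p_any, sys,
               tolerance = 1e-12)

  # latent compositions close to one
  traj <- tr$trajectories$unmarried[[code]]
  expect_true(all(abs(traj$modern + traj$traditional + traj$unmet +
                        traj$no_need - 1) < 1e-9))

  # marriage proportions decline over time
  for (cc in tr$meta$country_code[1:3]) {
    w <- tr$demography$prop_married[tr$demography$country_code == cc]
    expect_true(w[length(w)] < w[1])
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("country parameter draws centre on the hierarchy means", {
  # many countries; the sample mean of the logit any-method asymptote
  # must sit within 3 standard errors of the world prior mean
  cfg <- sim_config(n_regions = 8, n_subregions_per_region = 5,
                    n_countries_per_subregion = 10)
  tr <- simulate_truth(cfg, seed = 21)
  th <- tr$params$married[, "la_any"]
  mu0 <- cfg$hyper$root_mean[["la_any"]]
  # countries cluster in subregions and regions; the variance of the
  # grand mean is the sum of the level variances over level counts
  se <- sqrt(cfg$truth_sd$region[["la_any"]]^2 / 8 +
               cfg$truth_sd$subregion[["la_any"]]^2 / 40 +
               cfg$truth_sd$country[["la_any"]]^2 / 400)
  expect_lt(abs(mean(th) - mu0), 3 * se)
})

test_that("simulate_surveys: noise-free limit and zero inflation", {
  bp0 <- default_bias_params(
    nonsampling_sd = c(DHS = 0, MICS = 0, RHS = 0, WFS = 0, PMA = 0,
                       national = 0, other = 0),
    default_sampling_sd = 0)
  cfg <- sim_config(bias_params = bp0, baseline_flag_prob = 0,
                    misclass_flag_prob = 0, prob_se_present = 0)
  tr <- simulate_truth(cfg, seed = 8)
  obs <- simulate_surveys(tr, cfg, seed = 8)
  expect_gt(nrow(obs), 0)
  for (i in seq_len(min(nrow(obs), 20))) {
    o <- obs[i, ]
    traj <- tr$trajectories[[o$marital_group]][[o$country_code]]
    lat <- traj[which.min(abs(traj$year - o$ref_year)), ]
    expect_equal(o$p_any, lat$p_any, tolerance = 1e-9)
  }

  cfg1 <- sim_config(surveys_zero_inflation = 1)
  expect_equal(nrow(simulate_surveys(tr, cfg1, seed = 8)), 0)
})

test_that("every generated observation satisfies the record invariants", {
  cfg <- sim_config(baseline_flag_prob = 0.3, misclass_flag_prob = 0.3)
  tr <- simulate_truth(cfg, seed = 13)
  obs <- simulate_surveys(tr, cfg, seed = 13)
  for (col in c("p_any", "p_modern", "p_traditional", "p_unmet")) {
    v <- obs[[col]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  }
  all3 <- !is.na(obs$p_modern)
  expect_true(all(abs(obs$p_modern[all3] + obs$p_traditional[all3] -
                        obs$p_any[all3]) < 0.005))
  expect_true(all(obs$ref_year >= 1960 & obs$ref_year <= 2030))
  # and the reader accepts the generator output wholesale
  f <- tempfile(fileext = ".csv")
  write.csv(obs, f, row.names = FALSE)
  expect_equal(nrow(read_observations(f)), nrow(obs))
})

test_that("modern_inflated surveys inflate the modern share, not total use", {
  # one country, thousands of surveys, all misclassified
  cfg <- sim_config(n_regions = 1, n_subregions_per_region = 1,
                    n_countries_per_subregion = 2,
                    surveys_mean = 3000, surveys_zero_inflation = 0,
                    unmarried_factor = 0, baseline_flag_prob = 0,
                    misclass_flag_prob = 1, prob_modern_missing = 0,
                    ar_sd = 0)
  tr <- simulate_truth(cfg, seed = 31)
  obs <- simulate_surveys(tr, cfg, seed = 31)
  obs <- obs[obs$misclass_flags == "modern_inflated", ]
  expect_gt(nrow(obs), 300)
  lat <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    traj <- tr$trajectories$married[[obs$country_code[i]]]
    traj[which.min(abs(traj$year - obs$ref_year[i])), ]
  }))
  r_obs <- obs$p_modern / obs$p_any
  r_lat <- lat$modern / lat$p_any
  # modern share systematically above truth...
  expect_gt(mean(qlogis(r_obs) - qlogis(r_lat)),
            3 * sd(qlogis(r_obs) - qlogis(r_lat)) / sqrt(nrow(obs)))
  # ...while any-method use is unbiased within Monte-Carlo error
  d_any <- qlogis(obs$p_any) - qlogis(lat$p_any)
  expect_lt(abs(mean(d_any)), 4 * sd(d_any) / sqrt(nrow(obs)))
})

test_that("make_fixture writes a loadable, reproducible bundle", {
  cfg <- sim_config()
  d1 <- file.path(tempfile(), "f1"); d2 <- file.path(tempfile(), "f2")
  p1 <- make_fixture(cfg, 17, d1)
  p2 <- make_fixture(cfg, 17, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  obs <- read_observations(p1$observations)
  demog <- read_demography(p1$demography)
  meta <- read_country_meta(p1$metadata)
  expect_length(validate_dataset(obs, demog, meta)$issues, 0)
  expect_equal(nrow(meta), 12)

  # a designated country without surveys stays in the demography
  cfg0 <- sim_config(surveys_zero_inflation = 1)
  d3 <- file.path(tempfile(), "f3")
  p3 <- make_fixture(cfg0, 17, d3)
  expect_equal(nrow(read_observations(p3$observations)), 0)
  expect_gt(nrow(read_demography(p3$demography)), 0)
})
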