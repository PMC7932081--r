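# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

make_meta <- function(codes = c("AAA", "AAB"), subregion = "S1",
                      region = "R1", activity_group = 1L) {
  data.frame(country_code = codes, name = paste("Country", codes),
             subregion = subregion, region = region,
             income_group = NA_character_,
             development_group = NA_character_,
             activity_group = activity_group, stringsAsFactors = FALSE)
}

make_demog <- function(codes = c("AAA", "AAB"), years = 1970:2030,
                       pop = 1e5, w = 0.2) {
  do.call(rbind, lapply(codes, function(cc) {
    data.frame(country_code = cc, year = years, pop_15_19 = pop,
               prop_married = w, filled = FALSE)
  }))
}

empty_obs <- function() {
  data.frame(country_code = character(), marital_group = character(),
             ref_year = numeric(), p_any = numeric(),
             p_modern = numeric(), p_traditional = numeric(),
             p_unmet = numeric(), source_type = character(),
             se_any = numeric(), se_modern = numeric(),
             se_unmet = numeric(), baseline_flags = character(),
             misclass_flags = character(), stringsAsFactors = FALSE)
}

make_obs <- function(country = "AAA", group = "married", year = 2005.5,
                     p_any = 0.35, p_modern = NA, p_traditional = NA,
                     p_unmet = NA, source = "DHS", se_any = 0.02,
                     se_modern = NA, se_unmet = NA, baseline = "",
                     misclass = "") {
  data.frame(country_code = country, marital_group = group,
             ref_year = year, p_any = p_any, p_modern = p_modern,
             p_traditional = p_traditional, p_unmet = p_unmet,
             source_type = source, se_any = se_any,
             se_modern = se_modern, se_unmet = se_unmet,
             baseline_flags = baseline, misclass_flags = misclass,
             stringsAsFactors = FALSE)
}

# fixed-parameter vector freezing the whole model except `free`
oracle_fixed <- function(free = "theta.AAA.la_any",
                         nodes = c("world", "r:R1", "s:S1")) {
  fx <- c("theta.AAA.la_any" = 0, "theta.AAA.lr_any" = log(0.08),
          "theta.AAA.m_any" = 2000, "theta.AAA.la_ratio" = 1,
          "theta.AAA.lr_ratio" = log(0.08), "theta.AAA.m_ratio" = 2000,
          "theta.AAA.u_int" = -1.7, slope = 2, rho_any = 0.8,
          rho_ratio = 0.8, sd_any = 0.1, sd_ratio = 0.1)
  for (nd in nodes) {
    for (p in adolfp:::PARAM_NAMES) fx[paste0("mu.", nd, ".", p)] <- 0
  }
  for (lv in c("region", "subregion", "country")) {
    for (p in adolfp:::PARAM_NAMES) fx[paste0("sigma.", lv, ".", p)] <- 1
  }
  fx[setdiff(names(fx), free)]
}

# a light composition-draw object with constant composition per country
const_prop <- function(comp_by_country, years = 2019, n_draws = 200,
                       marital_group = "married") {
  countries <- names(comp_by_country)
  arr <- array(NA_real_, c(n_draws, length(countries), length(years), 4),
               dimnames = list(NULL, countries, years,
                               c("modern", "traditional", "unmet",
                                 "no_need")))
  for (i in seq_along(countries)) {
    for (j in seq_along(years)) {
      arr[, i, j, ] <- matrix(rep(comp_by_country[[i]], each = n_draws),
                              n_draws)
    }
  }
  adolfp:::fp_prop(arr, years, countries, marital_group)
}

# small fitted model reused across tests (memoised)
.fit_cache <- new.env(parent = emptyenv())
cached_small_fit <- function() {
  if (is.null(.fit_cache$smp)) {
    cfg <- sim_config(n_regions = 2, n_subregions_per_region = 1,
                      n_countries_per_subregion = 2, surveys_mean = 4,
                      surveys_zero_inflation = 0,
                      baseline_flag_prob = 0, misclass_flag_prob = 0)
    truth <- simulate_truth(cfg, seed = 99)
    obs <- simulate_surveys(truth, cfg, seed = 99)
    smp <- fit(obs, truth$demography, truth$meta, model_config(),
               mcmc_config(n_chains = 2, n_iterations = 800,
                           n_warmup = 400, thinning = 2, seed = 99),
               marital_group = "married")
    .fit_cache$truth <- truth
    .fit_cache$obs <- obs
    .fit_cache$smp <- smp
  }
  list(smp = .fit_cache$smp, truth = .fit_cache$truth,
       obs = .fit_cache$obs)
}
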