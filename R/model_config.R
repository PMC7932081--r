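# Model and sampler configuration objects.

#' Model configuration
#'
#' @param bias_params observation-model error/bias settings
#'   ([default_bias_params()]); when `estimate_bias` is `TRUE` the shift
#'   and misclassification parameters are sampled (zero-centred normal
#'   priors), otherwise they are held at these values. Non-sampling
#'   standard deviations are always held fixed.
#' @param estimate_bias sample bias/misclassification parameters jointly
#'   with the rest of the model (only if flagged observations exist).
#' @param priors hierarchical prior set ([default_hierarchy_priors()]).
#' @param slope_prior mean and sd of the normal prior on the shared
#'   unmet-link slope.
#' @param ar_sd_hn_scale half-normal scale of the AR(1) innovation sd
#'   prior (per component).
#' @param rho_max upper bound of the uniform prior on the AR(1)
#'   autocorrelation (stationarity requires < 1).
#' @param shift_prior_sd prior sd of the logit-scale bias shifts.
#' @param misclass_prior_sd prior sd of the misclassification reallocation
#'   parameters on the logit scale (prior centred at a reallocation of
#'   one half).
#' @param years full annual estimation/projection grid.
#' @param fixed named numeric vector of parameters to hold fixed, using
#'   the flat names of the posterior sample columns (e.g.
#'   `theta.AAA.la_any`, `mu.world.m_any`, `sigma.country.la_any`,
#'   `slope`, `rho_any`, `sd_ratio`, `shift_any.age_truncated`,
#'   `misclass.modern_inflated`). Used for toy models and oracle checks.
#' @return list of class `fp_model_config`.
#' @export
model_config <- function(bias_params = default_bias_params(),
                         estimate_bias = TRUE,
                         priors = default_hierarchy_priors(),
                         slope_prior = c(mean = 2, sd = 1),
                         ar_sd_hn_scale = 0.15,
                         rho_max = 0.99,
                         shift_prior_sd = 0.5,
                         misclass_prior_sd = 1,
                         years = 1970:2030,
                         fixed = numeric()) {
  structure(as.list(environment()), class = "fp_model_config")
}

#' MCMC configuration
#'
#' Defaults are desk-scale for panels of up to about 30 countries: 4
#' chains of 10,000 iterations with 5,000 discarded as warmup and thinning
#' by 5 (4,000 retained draws).
#'
#' @param n_chains number of chains (>= 2 required for convergence
#'   diagnostics).
#' @param n_iterations iterations per chain.
#' @param n_warmup warmup iterations discarded (adaptation is frozen at
#'   the end of warmup).
#' @param thinning keep every `thinning`-th post-warmup iteration.
#' @param seed integer seed; all chain streams derive from it.
#' @param target_accept Metropolis target acceptance rate for the
#'   Robbins-Monro scale adaptation.
#' @param rhat_threshold flagging threshold for split R-hat.
#' @return list of class `fp_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 10000,
                        n_warmup = 5000, thinning = 5, seed = 1,
                        target_accept = 0.234, rhat_threshold = 1.1) {
  if (n_warmup < 0 || n_iterations <= n_warmup) {
    stop("need n_iterations > n_warmup >= 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "fp_mcmc_config")
}
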