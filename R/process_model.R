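# Latent generative mechanics: logistic transition curves, the unmet-need
# link, AR(1) deviations, and assembly of the four-way composition
# (modern use, traditional use, unmet need, no need).

#' Logistic transition curve
#'
#' Systematic S-shaped trend used for contraceptive prevalence (any method)
#' and for the modern share of use. The curve rises from 0 towards a free
#' asymptote; countries that remain at low prevalence are represented by a
#' low asymptote or a midpoint far beyond the estimation window, so only a
#' portion of the curve is ever traversed.
#'
#' @param t numeric vector of (decimal) years.
#' @param asymptote long-run maximum level, in (0, 1].
#' @param rate growth rate per year, > 0.
#' @param midpoint year at which the curve reaches half its asymptote.
#' @return proportions, same length as `t`.
#' @examples
#' logistic_transition(2010, 0.6, 0.1, 2000)
#' @export
logistic_transition <- function(t, asymptote, rate, midpoint) {
  if (any(rate <= 0)) stop("rate must be > 0", call. = FALSE)
  if (any(asymptote <= 0 | asymptote > 1)) {
    stop("asymptote must lie in (0, 1]", call. = FALSE)
  }
  asymptote / (1 + exp(-rate * (t - midpoint)))
}

#' Unmet need among non-users as a function of total prevalence
#'
#' Unmet need is not given its own time trend: among women not using any
#' method, the proportion with unmet need is a monotone function of total
#' contraceptive prevalence. As prevalence rises, awareness of and demand
#' for contraception rise with it, so the conditional unmet-need proportion
#' increases; the population-level unmet share `(1 - p_any) * u` then rises
#' and eventually falls as use crowds out need.
#'
#' @param p_any total contraceptive prevalence, in \[0, 1\].
#' @param intercept country-level intercept on the logit scale.
#' @param slope shared (world-level) coefficient on prevalence.
#' @return proportion of non-users with unmet need.
#' @export
unmet_link <- function(p_any, intercept, slope) {
  stopifnot_prob(p_any, "p_any")
  invlogit(intercept + slope * p_any)
}

#' Assemble the four-way family planning composition
#'
#' Maps the three modelled quantities (total prevalence, modern share of
#' use, unmet need among non-users) to the four population shares, which
#' sum to one by construction.
#'
#' @param p_any total prevalence in \[0, 1\].
#' @param r_modern share of users using a modern method, in \[0, 1\].
#' @param u_nonusers share of non-users with unmet need, in \[0, 1\].
#' @return list with components `modern`, `traditional`, `unmet`, `no_need`
#'   (vectors if the inputs are vectors).
#' @export
compose_shares <- function(p_any, r_modern, u_nonusers) {
  stopifnot_prob(p_any, "p_any")
  stopifnot_prob(r_modern, "r_modern")
  stopifnot_prob(u_nonusers, "u_nonusers")
  list(
    modern      = p_any * r_modern,
    traditional = p_any * (1 - r_modern),
    unmet       = (1 - p_any) * u_nonusers,
    no_need     = (1 - p_any) * (1 - u_nonusers)
  )
}

#' Stationary AR(1) deviation series
#'
#' Draws a stationary first-order autoregressive path: the first value from
#' the stationary distribution N(0, sd^2 / (1 - rho^2)), subsequent values
#' recursively. Used for smoothing deviations around the systematic curves
#' and, conditionally, for projection beyond the data period.
#'
#' @param n_years length of the series.
#' @param rho autocorrelation, in \[0, 1).
#' @param sd innovation standard deviation, >= 0.
#' @param seed integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @return numeric vector of length `n_years`.
#' @export
ar1_deviations <- function(n_years, rho, sd, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  set.seed(seed)
  ar1_path(n_years, rho, sd)
}

# RNG-stream version (no set.seed) used inside larger simulations.
ar1_path <- function(n_years, rho, sd) {
  if (sd == 0) return(numeric(n_years))
  x <- numeric(n_years)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))
  if (n_years > 1) {
    e <- stats::rnorm(n_years - 1, 0, sd)
    for (i in 2:n_years) x[i] <- rho * x[i - 1] + e[i - 1]
  }
  x
}

#' Latent composition trajectory for one country
#'
#' Combines the systematic logistic curves with AR(1) deviations on the
#' logit scale and the unmet-need link, returning the annual composition.
#' The unmet link is evaluated at the deviated prevalence, so unmet need
#' inherits year-to-year variation through the link.
#'
#' @param params list with fields `asymptote_any`, `rate_any`,
#'   `midpoint_any`, `asymptote_ratio`, `rate_ratio`, `midpoint_ratio`,
#'   `unmet_intercept`, `unmet_slope` (see [default_transition_params()]).
#' @param years numeric year grid.
#' @param deviations_any,deviations_ratio deviation series aligned to
#'   `years` (defaults: zero).
#' @return data.frame with columns `year`, `p_any`, `r_modern`,
#'   `u_nonusers`, `modern`, `traditional`, `unmet`, `no_need`.
#' @export
latent_trajectory <- function(params, years,
                              deviations_any = numeric(length(years)),
                              deviations_ratio = numeric(length(years))) {
  if (length(deviations_any) != length(years) ||
      length(deviations_ratio) != length(years)) {
    stop("deviation series must be aligned to years", call. = FALSE)
  }
  sys_any <- logistic_transition(years, params$asymptote_any,
                                 params$rate_any, params$midpoint_any)
  sys_ratio <- logistic_transition(years, params$asymptote_ratio,
                                   params$rate_ratio, params$midpoint_ratio)
  p_any <- invlogit(logit(sys_any) + deviations_any)
  r_modern <- invlogit(logit(sys_ratio) + deviations_ratio)
  u <- unmet_link(p_any, params$unmet_intercept, params$unmet_slope)
  comp <- compose_shares(p_any, r_modern, u)
  data.frame(year = years, p_any = p_any, r_modern = r_modern,
             u_nonusers = u, modern = comp$modern,
             traditional = comp$traditional, unmet = comp$unmet,
             no_need = comp$no_need)
}

#' Template transition parameter set
#'
#' A plausible mid-transition country, used as a starting point in examples
#' and tests.
#'
#' @param ... overrides for individual fields.
#' @return named list of transition parameters.
#' @export
default_transition_params <- function(...) {
  p <- list(
    asymptote_any   = 0.6,
    rate_any        = 0.08,
    midpoint_any    = 2000,
    asymptote_ratio = 0.85,
    rate_ratio      = 0.08,
    midpoint_ratio  = 1995,
    unmet_intercept = logit(0.15),
    unmet_slope     = 2,
    ar_rho          = 0.8,
    ar_sd           = 0.1
  )
  modifyList(p, list(...))
}
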