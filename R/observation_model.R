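# Likelihood of survey observations given the latent composition,
# including additive logit-scale shifts for non-baseline samples and
# modern/traditional misclassification that preserves any-method use.

#' Bias and error parameters of the observation model
#'
#' Non-baseline samples (e.g. surveys restricted to ages 18+, or to a
#' geographic subset) receive additive shifts on the logit scale of total
#' prevalence and of unmet need among non-users; a logit-additive shift is
#' a multiplicative effect on the odds. Misclassification between modern
#' and traditional methods reallocates a fraction of the donor category
#' while leaving any-method use untouched. Each source type carries a
#' non-sampling standard deviation on the logit scale, added to the
#' delta-method sampling variance.
#'
#' @param shift_any,shift_u named numeric vectors over the baseline flags
#'   (`age_truncated`, `geographic_subset`, `other_nonbaseline`): additive
#'   logit-scale shifts applied to flagged observations.
#' @param misclass_realloc named numeric vector over the misclassification
#'   flags (`modern_inflated`, `traditional_inflated`, `methods_combined`):
#'   fraction of the donor share reallocated.
#' @param nonsampling_sd named numeric vector over source types, >= 0,
#'   logit scale.
#' @param default_sampling_sd logit-scale sampling sd used when a record
#'   carries no standard error.
#' @param boundary_n effective sample size for the 1/(2n) boundary
#'   correction of observed proportions equal to 0 or 1.
#' @return object of class `bias_params`.
#' @export
default_bias_params <- function(shift_any = c(age_truncated = 0.25,
                                              geographic_subset = -0.15,
                                              other_nonbaseline = 0.1),
                                shift_u = c(age_truncated = 0.2,
                                            geographic_subset = -0.1,
                                            other_nonbaseline = 0.1),
                                misclass_realloc = c(modern_inflated = 0.3,
                                                     traditional_inflated = 0.3,
                                                     methods_combined = 0.8),
                                nonsampling_sd = c(DHS = 0.10, MICS = 0.12,
                                                   RHS = 0.15, WFS = 0.15,
                                                   PMA = 0.12, national = 0.20,
                                                   other = 0.25),
                                default_sampling_sd = 0.15,
                                boundary_n = 1000) {
  stopifnot(all(BASELINE_FLAGS %in% names(shift_any)),
            all(BASELINE_FLAGS %in% names(shift_u)),
            all(MISCLASS_FLAGS %in% names(misclass_realloc)),
            all(SOURCE_TYPES %in% names(nonsampling_sd)),
            all(nonsampling_sd >= 0))
  structure(list(shift_any = shift_any, shift_u = shift_u,
                 misclass_realloc = misclass_realloc,
                 nonsampling_sd = nonsampling_sd,
                 default_sampling_sd = default_sampling_sd,
                 boundary_n = boundary_n),
            class = "bias_params")
}

#' Expected observed summaries for a flagged survey
#'
#' Applies misclassification reallocation on the proportion scale, then
#' bias shifts on the logit scale, and returns both the adjusted shares and
#' the logit-scale expectations of the three transformed summaries
#' (any-method use, modern share of use, unmet need among non-users).
#'
#' @param latent list with `modern`, `traditional`, `unmet`, `no_need`
#'   (one composition), or the output row of [latent_trajectory()].
#' @param flags character vector, subset of the defined baseline and
#'   misclassification flags.
#' @param bias_params a [default_bias_params()] object.
#' @return list with `modern`, `traditional`, `p_any` (proportion scale,
#'   after misclassification) and `z_any`, `z_ratio`, `z_u` (logit scale,
#'   after bias shifts).
#' @export
expected_observation <- function(latent, flags = character(), bias_params) {
  known <- c(BASELINE_FLAGS, MISCLASS_FLAGS)
  if (length(flags) && !all(flags %in% known)) {
    stop("unknown flag(s): ", paste(setdiff(flags, known), collapse = ", "),
         call. = FALSE)
  }
  modern <- latent$modern
  trad   <- latent$traditional
  p_any  <- modern + trad
  unmet  <- latent$unmet

  # misclassification: move mass between the two method categories,
  # keeping any-method use fixed
  g <- bias_params$misclass_realloc
  if ("modern_inflated" %in% flags) {
    modern <- modern + g[["modern_inflated"]] * trad
    trad   <- p_any - modern
  }
  if ("traditional_inflated" %in% flags) {
    trad   <- trad + g[["traditional_inflated"]] * modern
    modern <- p_any - trad
  }
  if ("methods_combined" %in% flags) {
    modern <- modern + g[["methods_combined"]] * trad
    trad   <- p_any - modern
  }

  n <- bias_params$boundary_n
  u <- if (p_any < 1) unmet / (1 - p_any) else 0.5
  r <- if (p_any > 0) modern / p_any else 0.5
  z_any   <- logit(correct_boundary(p_any, n))
  z_ratio <- logit(correct_boundary(r, n))
  z_u     <- logit(correct_boundary(u, n))

  for (f in intersect(flags, BASELINE_FLAGS)) {
    z_any <- z_any + bias_params$shift_any[[f]]
    z_u   <- z_u + bias_params$shift_u[[f]]
  }

  list(modern = modern, traditional = trad, p_any = p_any,
       z_any = z_any, z_ratio = z_ratio, z_u = z_u)
}

#' Delta-method sampling variance on the logit scale
#'
#' @param p proportion in (0, 1); boundary values receive the 1/(2n)
#'   correction first.
#' @param se sampling standard error on the proportion scale, >= 0.
#' @param boundary_n effective sample size for the boundary correction.
#' @return variance of logit(p-hat).
#' @export
sampling_variance_logit <- function(p, se, boundary_n = 1000) {
  if (any(se < 0)) stop("se must be >= 0", call. = FALSE)
  p <- correct_boundary(p, boundary_n)
  (se / (p * (1 - p)))^2
}

# Transformed observed summaries and their total variances for one record.
# Returns a list of terms, one per present indicator, each with fields
# z (observed, logit scale), which ("any"/"ratio"/"u"), var_sampling.
# The ratio term needs p_any present; p_unmet is re-based to non-users.
transformed_summaries <- function(obs, bias_params) {
  n <- bias_params$boundary_n
  terms <- list()
  p_any <- obs$p_any
  if (!is.null(p_any) && !is.na(p_any)) {
    pa <- correct_boundary(p_any, n)
    v <- if (!is.null(obs$se_any) && !is.na(obs$se_any) && obs$se_any > 0) {
      sampling_variance_logit(p_any, obs$se_any, n)
    } else NA_real_
    terms$any <- list(z = logit(pa), which = "any", var_sampling = v)

    pm <- obs$p_modern
    if (!is.null(pm) && !is.na(pm) && p_any > 0) {
      r <- correct_boundary(pm / max(p_any, 1 / (2 * n)), n)
      v <- if (!is.null(obs$se_modern) && !is.na(obs$se_modern) && obs$se_modern > 0) {
        sampling_variance_logit(r, obs$se_modern / max(p_any, 1 / (2 * n)), n)
      } else NA_real_
      terms$ratio <- list(z = logit(r), which = "ratio", var_sampling = v)
    }
  }
  pu <- obs$p_unmet
  if (!is.null(pu) && !is.na(pu)) {
    base <- if (!is.null(p_any) && !is.na(p_any)) max(1 - p_any, 1 / (2 * n)) else 1
    u <- correct_boundary(pu / base, n)
    v <- if (!is.null(obs$se_unmet) && !is.na(obs$se_unmet) && obs$se_unmet > 0) {
      sampling_variance_logit(u, obs$se_unmet / base, n)
    } else NA_real_
    terms$u <- list(z = logit(u), which = "u", var_sampling = v)
  }
  terms
}

# Total observation variance for one term of one record.
total_obs_variance <- function(term, source_type, bias_params) {
  vs <- term$var_sampling
  if (is.na(vs)) vs <- bias_params$default_sampling_sd^2
  ns <- bias_params$nonsampling_sd[[source_type]]
  vs + ns^2
}

#' Log-likelihood of one survey observation
#'
#' Independent normal log-densities on the logit scale, one per present
#' indicator, centred at the bias/misclassification-adjusted expectation of
#' the latent composition. The total variance is the delta-method
#' transformed sampling variance (source-type default when no standard
#' error is recorded) plus the squared source-type non-sampling standard
#' deviation.
#'
#' @param obs a survey observation (one row of [read_observations()] as a
#'   list, or any list with the same fields).
#' @param latent the latent composition at the observation year.
#' @param bias_params a [default_bias_params()] object.
#' @return scalar log-density.
#' @export
observation_loglik <- function(obs, latent, bias_params) {
  flags <- unlist(lapply(c(obs$baseline_flags %||% character(),
                           obs$misclass_flags %||% character()),
                         parse_flags))
  ex <- expected_observation(latent, flags, bias_params)
  terms <- transformed_summaries(obs, bias_params)
  if (!length(terms)) stop("no indicator present in observation", call. = FALSE)
  ll <- 0
  for (term in terms) {
    v <- total_obs_variance(term, obs$source_type, bias_params)
    if (v <= 0) stop("total observation variance must be > 0", call. = FALSE)
    mu <- switch(term$which, any = ex$z_any, ratio = ex$z_ratio, u = ex$z_u)
    ll <- ll + stats::dnorm(term$z, mean = mu, sd = sqrt(v), log = TRUE)
  }
  ll
}
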