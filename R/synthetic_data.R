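# Synthetic world generator: a hierarchy of regions, subregions and
# countries with latent logistic transitions, declining marriage
# proportions, and survey observations carrying the defects the analysis
# must absorb: mixed source types with different error variances,
# zero-inflated survey availability (some countries have no surveys, some
# more than five), non-baseline sampling flags, and modern/traditional
# misclassification.

#' Simulation configuration
#'
#' Defaults describe a small world of 2 regions x 2 subregions x 3
#' countries (12 countries). Survey counts per country and marital group
#' are zero-inflated Poisson; the source-type mix follows the observed
#' distribution of the adolescent survey compilation (DHS-dominated).
#' Observation noise is applied on the logit scale; flagged records
#' receive the configured additive bias and misclassification
#' reallocations, which double as the true values a fit should recover.
#'
#' @param n_regions,n_subregions_per_region,n_countries_per_subregion
#'   world dimensions.
#' @param years annual estimation grid.
#' @param survey_year_range years within which surveys are fielded.
#' @param surveys_mean mean surveys per country (married; unmarried gets
#'   `unmarried_factor` times that).
#' @param surveys_zero_inflation probability a country has no surveys at
#'   all for a group.
#' @param unmarried_factor multiplier on `surveys_mean` for unmarried
#'   women (fewer surveys report them).
#' @param source_mix named probabilities over the source types.
#' @param baseline_flag_prob,misclass_flag_prob probability a survey is a
#'   non-baseline sample / misclassifies methods.
#' @param prob_se_present probability a record carries sampling standard
#'   errors.
#' @param se_any,se_modern,se_unmet proportion-scale sampling standard
#'   errors when present.
#' @param prob_modern_missing,prob_unmet_missing probability the record
#'   omits the method split / the unmet-need measurement.
#' @param bias_params true bias/error parameters
#'   ([default_bias_params()]).
#' @param unmet_slope shared world-level unmet-link slope.
#' @param ar_rho,ar_sd AR(1) deviation parameters (shared across
#'   countries).
#' @param frac_group0 fraction of subregions in sexual-activity group 0
#'   (low activity; depresses unmarried prevalence).
#' @param group0_shift downward shift of the unmarried any-method
#'   asymptote (logit scale) in group-0 subregions.
#' @param truth_sd named list of level sds used when drawing parameters
#'   down the hierarchy (defaults: moderate heterogeneity).
#' @param hyper hierarchy prior set; world means for the truth draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 2,
                       n_subregions_per_region = 2,
                       n_countries_per_subregion = 3,
                       years = 1970:2030,
                       survey_year_range = c(1975, 2019),
                       surveys_mean = 4,
                       surveys_zero_inflation = 0.15,
                       unmarried_factor = 0.6,
                       source_mix = c(DHS = 0.42, MICS = 0.18, RHS = 0.06,
                                      WFS = 0.04, PMA = 0.05,
                                      national = 0.10, other = 0.15),
                       baseline_flag_prob = 0.15,
                       misclass_flag_prob = 0.10,
                       prob_se_present = 0.7,
                       se_any = 0.015, se_modern = 0.012, se_unmet = 0.015,
                       prob_modern_missing = 0.2,
                       prob_unmet_missing = 0.4,
                       bias_params = default_bias_params(),
                       unmet_slope = 2,
                       ar_rho = 0.8, ar_sd = 0.1,
                       frac_group0 = 0.25,
                       group0_shift = -2.5,
                       truth_sd = NULL,
                       hyper = default_hierarchy_priors()) {
  n_countries <- n_regions * n_subregions_per_region *
    n_countries_per_subregion
  if (n_countries < 2) stop("need at least 2 countries", call. = FALSE)
  probs <- c(surveys_zero_inflation, baseline_flag_prob,
             misclass_flag_prob, prob_se_present, prob_modern_missing,
             prob_unmet_missing, frac_group0, source_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(truth_sd)) {
    truth_sd <- list(
      region    = c(la_any = 0.4, lr_any = 0.2, m_any = 8,
                    la_ratio = 0.4, lr_ratio = 0.2, m_ratio = 8,
                    u_int = 0.4),
      subregion = c(la_any = 0.3, lr_any = 0.15, m_any = 6,
                    la_ratio = 0.3, lr_ratio = 0.15, m_ratio = 6,
                    u_int = 0.3),
      country   = c(la_any = 0.3, lr_any = 0.15, m_any = 5,
                    la_ratio = 0.3, lr_ratio = 0.15, m_ratio = 5,
                    u_int = 0.3)
    )
  }
  structure(as.list(environment()), class = "sim_config")
}

iso_codes <- function(n) {
  # synthetic ISO-like alpha-3 codes AAA, AAB, ...
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1
  paste0(LETTERS[i %/% 676 + 1], LETTERS[(i %/% 26) %% 26 + 1],
         LETTERS[i %% 26 + 1])
}

#' Simulate the latent truth bundle
#'
#' Draws country parameters down the hierarchy (world -> region ->
#' subregion -> country, with unmarried group-0 subregions shifted to low
#' any-method asymptotes), produces latent annual composition trajectories
#' with AR(1) deviations, a declining marriage proportion per country, and
#' the metadata table.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory).
#' @return list of class `truth_bundle` with `meta`, `demography`,
#'   `params` (per marital group, country: transition parameters),
#'   `trajectories` (per group: list of [latent_trajectory()] frames),
#'   and `config`.
#' @export
simulate_truth <- function(config, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(derive_seed(seed, "truth"))
  nR <- config$n_regions
  nS <- config$n_subregions_per_region
  nC <- config$n_countries_per_subregion
  n  <- nR * nS * nC
  codes <- iso_codes(n)
  region <- rep(paste0("Region", seq_len(nR)), each = nS * nC)
  subregion <- rep(paste0("Subregion", seq_len(nR * nS)), each = nC)

  sub_names <- unique(subregion)
  n_g0 <- round(config$frac_group0 * length(sub_names))
  g0_subs <- if (n_g0 > 0) sample(sub_names, n_g0) else character()
  act <- ifelse(subregion %in% g0_subs, 0L, 1L)

  meta <- data.frame(country_code = codes, name = paste("Country", codes),
                     subregion = subregion, region = region,
                     income_group = sample(c("low", "lower-middle",
                                             "upper-middle", "high"),
                                           n, replace = TRUE),
                     development_group = sample(c("less developed",
                                                  "more developed"),
                                                n, replace = TRUE),
                     activity_group = act, stringsAsFactors = FALSE)
  class(meta) <- c("fp_meta", "data.frame")

  years <- config$years
  hy <- config$hyper
  sd_lv <- config$truth_sd

  draw_params <- function(group) {
    world <- hy$root_mean
    if (group == "unmarried") {
      # unmarried adolescents: lower prevalence overall, later transition
      world["la_any"] <- world["la_any"] - 1
      world["m_any"] <- world["m_any"] + 5
      world["u_int"] <- world["u_int"] - 0.7
    }
    region_eff <- vapply(PARAM_NAMES, function(p) {
      stats::rnorm(nR, world[p], sd_lv$region[p])
    }, numeric(nR))
    region_eff <- matrix(region_eff, nrow = nR,
                         dimnames = list(NULL, PARAM_NAMES))
    sub_eff <- vapply(PARAM_NAMES, function(p) {
      stats::rnorm(nR * nS, rep(region_eff[, p], each = nS),
                   sd_lv$subregion[p])
    }, numeric(nR * nS))
    sub_eff <- matrix(sub_eff, nrow = nR * nS,
                      dimnames = list(NULL, PARAM_NAMES))
    th <- vapply(PARAM_NAMES, function(p) {
      stats::rnorm(n, rep(sub_eff[, p], each = nC), sd_lv$country[p])
    }, numeric(n))
    rownames(th) <- codes
    if (group == "unmarried") {
      th[act == 0L, "la_any"] <- th[act == 0L, "la_any"] +
        config$group0_shift
    }
    th
  }

  make_trajs <- function(th) {
    out <- vector("list", n)
    names(out) <- codes
    for (i in seq_len(n)) {
      p <- theta_to_params(th[i, ], config$unmet_slope,
                           config$ar_rho, config$ar_sd)
      dev_any <- ar1_path(length(years), config$ar_rho, config$ar_sd)
      dev_ratio <- ar1_path(length(years), config$ar_rho, config$ar_sd)
      out[[i]] <- latent_trajectory(p, years, dev_any, dev_ratio)
    }
    out
  }

  params <- list(); trajectories <- list()
  for (g in MARITAL_GROUPS) {
    params[[g]] <- draw_params(g)
    trajectories[[g]] <- make_trajs(params[[g]])
  }

  # demography: log population with country-specific growth; marriage
  # proportion declining along a logistic in time
  pop0 <- exp(stats::rnorm(n, 13, 1))
  growth <- stats::rnorm(n, 0.01, 0.005)
  w0 <- invlogit(stats::rnorm(n, logit(0.25), 0.5))
  w_end <- w0 * stats::runif(n, 0.3, 0.6)
  wmid <- stats::runif(n, 1995, 2010)
  wrate <- stats::runif(n, 0.05, 0.12)
  demog <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(country_code = codes[i], year = years,
               pop_15_19 = pop0[i] * exp(growth[i] * (years - years[1])),
               prop_married = w_end[i] + (w0[i] - w_end[i]) /
                 (1 + exp(wrate[i] * (years - wmid[i]))),
               filled = FALSE)
  }))
  class(demog) <- c("fp_demography", "data.frame")

  structure(list(meta = meta, demography = demog, params = params,
                 trajectories = trajectories, config = config,
                 seed = seed),
            class = "truth_bundle")
}

# unconstrained 7-vector -> transition parameter list
theta_to_params <- function(th, unmet_slope, ar_rho, ar_sd) {
  list(asymptote_any = invlogit(th[["la_any"]]),
       rate_any = exp(th[["lr_any"]]),
       midpoint_any = th[["m_any"]],
       asymptote_ratio = invlogit(th[["la_ratio"]]),
       rate_ratio = exp(th[["lr_ratio"]]),
       midpoint_ratio = th[["m_ratio"]],
       unmet_intercept = th[["u_int"]],
       unmet_slope = unmet_slope, ar_rho = ar_rho, ar_sd = ar_sd)
}

#' Simulate survey observations around the latent truth
#'
#' Survey counts per country and marital group are zero-inflated Poisson.
#' Observation proportions are drawn around the latent composition on the
#' logit scale with source-type-specific total variance (delta-method
#' sampling variance when a standard error is attached, plus the
#' non-sampling variance of the source type). Flagged records receive the
#' configured additive bias on the logit scale; misclassified records move
#' mass between modern and traditional while preserving any-method use.
#'
#' @param truth a [simulate_truth()] bundle.
#' @param config the same [sim_config()].
#' @param seed integer seed.
#' @return `fp_observations` data.frame.
#' @export
simulate_surveys <- function(truth, config, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(derive_seed(seed, "surveys"))
  bp <- config$bias_params
  years <- config$years
  rows <- list()
  for (g in MARITAL_GROUPS) {
    mean_n <- config$surveys_mean *
      if (g == "unmarried") config$unmarried_factor else 1
    for (code in truth$meta$country_code) {
      n_surv <- if (stats::runif(1) < config$surveys_zero_inflation) 0L
                else stats::rpois(1, mean_n)
      if (n_surv == 0L) next
      traj <- truth$trajectories[[g]][[code]]
      yr <- sample(seq(config$survey_year_range[1],
                       config$survey_year_range[2]), n_surv,
                   replace = TRUE) + 0.5
      for (y in yr) {
        lat <- traj[which.min(abs(traj$year - y)), ]
        src <- sample(names(config$source_mix), 1,
                      prob = config$source_mix)
        bl <- if (stats::runif(1) < config$baseline_flag_prob) {
          sample(BASELINE_FLAGS, 1)
        } else character()
        mc <- if (stats::runif(1) < config$misclass_flag_prob) {
          sample(MISCLASS_FLAGS, 1)
        } else character()
        ex <- expected_observation(lat, c(bl, mc), bp)
        se_here <- stats::runif(1) < config$prob_se_present
        draw_z <- function(z, se, p_at) {
          vs <- if (se_here && !is.na(se)) {
            sampling_variance_logit(p_at, se, bp$boundary_n)
          } else bp$default_sampling_sd^2
          stats::rnorm(1, z, sqrt(vs + bp$nonsampling_sd[[src]]^2))
        }
        p_any_obs <- invlogit(draw_z(ex$z_any, config$se_any,
                                     correct_boundary(ex$p_any,
                                                      bp$boundary_n)))
        has_modern <- stats::runif(1) >= config$prob_modern_missing
        has_unmet <- stats::runif(1) >= config$prob_unmet_missing
        p_mod <- p_trad <- NA_real_
        if (has_modern) {
          r_lat <- correct_boundary(
            ex$modern / max(ex$p_any, 1e-6), bp$boundary_n)
          r_obs <- invlogit(draw_z(ex$z_ratio,
                                   config$se_modern / max(p_any_obs, 0.01),
                                   r_lat))
          p_mod <- p_any_obs * r_obs
          p_trad <- p_any_obs - p_mod
        }
        p_unmet <- NA_real_
        if (has_unmet) {
          u_lat <- correct_boundary(
            lat$unmet / max(1 - ex$p_any, 1e-6), bp$boundary_n)
          u_obs <- invlogit(draw_z(ex$z_u,
                                   config$se_unmet /
                                     max(1 - p_any_obs, 0.01), u_lat))
          p_unmet <- (1 - p_any_obs) * u_obs
        }
        rows[[length(rows) + 1]] <- data.frame(
          country_code = code, marital_group = g, ref_year = y,
          p_any = p_any_obs, p_modern = p_mod, p_traditional = p_trad,
          p_unmet = p_unmet, source_type = src,
          se_any = if (se_here) config$se_any else NA_real_,
          se_modern = if (se_here && has_modern) config$se_modern
                      else NA_real_,
          se_unmet = if (se_here && has_unmet) config$se_unmet
                     else NA_real_,
          baseline_flags = paste(bl, collapse = ";"),
          misclass_flags = paste(mc, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(country_code = character(), marital_group = character(),
               ref_year = numeric(), p_any = numeric(),
               p_modern = numeric(), p_traditional = numeric(),
               p_unmet = numeric(), source_type = character(),
               se_any = numeric(), se_modern = numeric(),
               se_unmet = numeric(), baseline_flags = character(),
               misclass_flags = character(), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("fp_observations", "data.frame")
  df
}

#' Write a complete synthetic fixture to disk
#'
#' Writes `observations.csv`, `demography.csv`, `metadata.csv` and
#' `truth_params.csv` (the latent parameters, for recovery tests) into
#' `outdir`; all files load cleanly through the readers and validate
#' without issues. Byte-identical output for identical config and seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param outdir writable directory (created if absent).
#' @return invisible named list of file paths.
#' @export
make_fixture <- function(config, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config, seed)
  obs <- simulate_surveys(truth, config, seed)
  paths <- list(
    observations = file.path(outdir, "observations.csv"),
    demography = file.path(outdir, "demography.csv"),
    metadata = file.path(outdir, "metadata.csv"),
    truth = file.path(outdir, "truth_params.csv")
  )
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
    df
  }
  utils::write.csv(fmt(as.data.frame(obs)), paths$observations,
                   row.names = FALSE, quote = TRUE)
  dem <- as.data.frame(truth$demography)
  dem$filled <- NULL
  utils::write.csv(fmt(dem), paths$demography, row.names = FALSE,
                   quote = TRUE)
  utils::write.csv(as.data.frame(truth$meta), paths$metadata,
                   row.names = FALSE, quote = TRUE)
  tp <- do.call(rbind, lapply(MARITAL_GROUPS, function(g) {
    th <- truth$params[[g]]
    data.frame(country_code = rep(rownames(th), ncol(th)),
               marital_group = g,
               param = rep(colnames(th), each = nrow(th)),
               value = as.vector(th), stringsAsFactors = FALSE)
  }))
  utils::write.csv(fmt(tp), paths$truth, row.names = FALSE, quote = TRUE)
  invisible(paths)
}
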