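# Out-of-sample validation: deterministic holdout splits and predictive
# coverage of held-out survey observations. Predictive intervals are for
# new observations (latent trajectory plus observation error), since that
# is what a held-out survey realises.

#' Split observations into train and test sets
#'
#' Rules: `"last_observation_per_country"` holds out each country's most
#' recent observation per marital group, except for countries with a
#' single observation, which stay entirely in the training set (a country
#' is never left dataless). `list(rule = "after_year", year = Y)` holds
#' out all observations with reference year beyond `Y`.
#'
#' @param observations `fp_observations` table.
#' @param rule `"last_observation_per_country"` or
#'   `list(rule = "after_year", year = Y)`.
#' @return list with `train` and `test` (both `fp_observations`); an
#'   empty test set triggers a message.
#' @export
holdout_split <- function(observations,
                          rule = "last_observation_per_country") {
  n <- nrow(observations)
  test_idx <- integer()
  if (identical(rule, "last_observation_per_country")) {
    groups <- split(seq_len(n),
                    paste(observations$country_code,
                          observations$marital_group))
    for (idx in groups) {
      if (length(idx) >= 2) {
        test_idx <- c(test_idx, idx[which.max(observations$ref_year[idx])])
      }
    }
  } else if (is.list(rule) && identical(rule$rule, "after_year")) {
    test_idx <- which(observations$ref_year > rule$year)
  } else {
    stop("unknown holdout rule", call. = FALSE)
  }
  test_idx <- sort(test_idx)
  if (!length(test_idx)) {
    message("holdout rule produced an empty test set")
  }
  list(train = observations[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = observations[test_idx, , drop = FALSE])
}

# Posterior predictive draws (proportion scale) for one held-out record:
# latent composition draws at the observation year, bias shifts from the
# per-draw bias parameters, plus logit-normal observation noise with the
# record's total variance.
predictive_draws_obs <- function(smp, obs_row) {
  o <- as.list(obs_row)
  bp <- smp$model_cfg$bias_params
  params <- smp$params
  i <- match(o$country_code, smp$countries)
  if (is.na(i)) stop("country not in fitted samples", call. = FALSE)
  j <- which.min(abs(smp$years - o$ref_year))
  mod <- smp$comp[, i, j, 1]; trad <- smp$comp[, i, j, 2]
  unm <- smp$comp[, i, j, 3]
  p_any <- mod + trad
  r <- ifelse(p_any > 0, mod / p_any, 0.5)
  u <- ifelse(p_any < 1, unm / (1 - p_any), 0.5)
  bl <- parse_flags(o$baseline_flags)
  mc <- parse_flags(o$misclass_flags)
  n_draws <- nrow(params)

  g <- cbind(params[, "misclass.modern_inflated"],
             params[, "misclass.traditional_inflated"],
             params[, "misclass.methods_combined"])
  if ("modern_inflated" %in% mc) r <- r + g[, 1] * (1 - r)
  if ("traditional_inflated" %in% mc) r <- r * (1 - g[, 2])
  if ("methods_combined" %in% mc) r <- r + g[, 3] * (1 - r)

  z_any <- logit(correct_boundary(p_any, bp$boundary_n))
  z_r <- logit(correct_boundary(r, bp$boundary_n))
  z_u <- logit(correct_boundary(u, bp$boundary_n))
  for (f in bl) {
    z_any <- z_any + params[, paste0("shift_any.", f)]
    z_u <- z_u + params[, paste0("shift_u.", f)]
  }
  terms <- transformed_summaries(o, bp)
  out <- list()
  if (!is.null(terms$any)) {
    v <- total_obs_variance(terms$any, o$source_type, bp)
    out$p_any <- invlogit(stats::rnorm(n_draws, z_any, sqrt(v)))
  }
  if (!is.null(terms$ratio) && !is.null(out$p_any)) {
    v <- total_obs_variance(terms$ratio, o$source_type, bp)
    out$p_modern <- out$p_any *
      invlogit(stats::rnorm(n_draws, z_r, sqrt(v)))
  }
  if (!is.null(terms$u)) {
    v <- total_obs_variance(terms$u, o$source_type, bp)
    base <- if (!is.null(out$p_any)) 1 - out$p_any else 1 - p_any
    out$p_unmet <- base * invlogit(stats::rnorm(n_draws, z_u, sqrt(v)))
  }
  out
}

#' Predictive coverage of held-out observations
#'
#' For each test observation and each present indicator, draws from the
#' posterior predictive distribution of a new observation and checks
#' whether the held-out value lies inside the central 95% predictive
#' interval. Reports empirical coverage, median error (predictive median
#' minus observed, proportion scale) and median absolute error, per
#' indicator and pooled.
#'
#' @param test held-out `fp_observations`.
#' @param smp `fp_samples` from the training fit (single marital group),
#'   or a named list with elements `married` and `unmarried`.
#' @param seed integer seed for the predictive noise.
#' @return list of class `fp_coverage` with `by_indicator`, `pooled`,
#'   and the per-point results.
#' @export
coverage_report <- function(test, smp, seed = 1) {
  if (!nrow(test)) stop("empty test set", call. = FALSE)
  set.seed(derive_seed(seed, "coverage"))
  get_smp <- function(g) {
    if (inherits(smp, "fp_samples")) {
      if (smp$marital_group != g) {
        stop("test contains group '", g, "' but samples are for '",
             smp$marital_group, "'", call. = FALSE)
      }
      smp
    } else smp[[g]]
  }
  rows <- list()
  for (i in seq_len(nrow(test))) {
    o <- test[i, , drop = FALSE]
    s <- get_smp(o$marital_group)
    pd <- predictive_draws_obs(s, o)
    for (ind in names(pd)) {
      observed <- o[[ind]]
      if (is.na(observed)) next
      qv <- stats::quantile(pd[[ind]], c(0.025, 0.5, 0.975),
                            names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        country_code = o$country_code, ref_year = o$ref_year,
        marital_group = o$marital_group, indicator = ind,
        observed = observed, pred_median = qv[2], lo = qv[1], hi = qv[3],
        covered = observed >= qv[1] & observed <= qv[3],
        stringsAsFactors = FALSE)
    }
  }
  pts <- do.call(rbind, rows)
  summarise_block <- function(d) {
    data.frame(n = nrow(d),
               coverage = mean(d$covered),
               median_error = stats::median(d$pred_median - d$observed),
               median_abs_error = stats::median(abs(d$pred_median -
                                                      d$observed)))
  }
  by_ind <- do.call(rbind, lapply(split(pts, pts$indicator),
                                  summarise_block))
  structure(list(by_indicator = by_ind, pooled = summarise_block(pts),
                 points = pts),
            class = "fp_coverage")
}
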