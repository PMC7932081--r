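# Transformation of posterior composition draws into reported
# indicators: marital-group weighting to all women, count conversion,
# draw-level aggregation, SDG 3.7.1, summaries with the median-identity
# adjustment, suppression, and the adolescent share of all women of
# reproductive age.

# light container for composition draws (proportion scale)
fp_prop <- function(comp, years, countries, marital_group) {
  structure(list(comp = comp, years = years, countries = countries,
                 marital_group = marital_group),
            class = "fp_prop_samples")
}

# prop_married weight matrix [country, year] aligned to a sample object
weight_matrix <- function(demography, countries, years) {
  w <- matrix(NA_real_, length(countries), length(years),
              dimnames = list(countries, years))
  for (i in seq_along(countries)) {
    d <- demography[demography$country_code == countries[i], ]
    idx <- match(years, d$year)
    if (anyNA(idx)) {
      stop("demography does not cover years for ", countries[i],
           call. = FALSE)
    }
    w[i, ] <- d$prop_married[idx]
  }
  w
}

pop_matrix <- function(demography, countries, years,
                       column = "pop_15_19") {
  p <- matrix(NA_real_, length(countries), length(years),
              dimnames = list(countries, years))
  for (i in seq_along(countries)) {
    d <- demography[demography$country_code == countries[i], ]
    idx <- match(years, d$year)
    if (anyNA(idx)) {
      stop("missing population years for ", countries[i], call. = FALSE)
    }
    p[i, ] <- d[[column]][idx]
  }
  p
}

#' Combine married and unmarried draws into all-women draws
#'
#' Per draw, country and year, the all-women composition is the
#' marriage-proportion-weighted sum of the married and unmarried
#' compositions. Weighting at the draw level yields a proper joint
#' posterior for all-women indicators.
#'
#' @param married,unmarried `fp_samples` (or `fp_prop_samples`) objects
#'   on the same draw grid.
#' @param demography `fp_demography` covering the sample years.
#' @return `fp_prop_samples` with `marital_group = "all"`.
#' @export
combine_marital <- function(married, unmarried, demography) {
  if (!identical(dim(married$comp), dim(unmarried$comp)) ||
      !identical(married$countries, unmarried$countries) ||
      !identical(married$years, unmarried$years)) {
    stop("married and unmarried draws are not on the same grid",
         call. = FALSE)
  }
  w <- weight_matrix(demography, married$countries, married$years)
  comp <- married$comp
  for (k in seq_len(dim(comp)[4])) {
    for (i in seq_along(married$countries)) {
      wm <- matrix(w[i, ], nrow = dim(comp)[1], ncol = dim(comp)[3],
                   byrow = TRUE)
      comp[, i, , k] <- wm * married$comp[, i, , k] +
        (1 - wm) * unmarried$comp[, i, , k]
    }
  }
  fp_prop(comp, married$years, married$countries, "all")
}

#' Convert proportion draws into count draws
#'
#' Counts are proportions times the relevant female population aged
#' 15-19: the married population (`prop_married * pop_15_19`) for married
#' samples, its complement for unmarried samples, and the full population
#' for all-women samples.
#'
#' @param samples `fp_samples` or `fp_prop_samples`.
#' @param demography `fp_demography`.
#' @return object of class `fp_counts`: count draw array, the group
#'   population matrix, and grid metadata.
#' @export
counts_from_proportions <- function(samples, demography) {
  countries <- samples$countries
  years <- samples$years
  pop <- pop_matrix(demography, countries, years)
  w <- weight_matrix(demography, countries, years)
  gpop <- switch(samples$marital_group,
                 married = w * pop,
                 unmarried = (1 - w) * pop,
                 all = pop,
                 stop("unknown marital group", call. = FALSE))
  count <- samples$comp
  for (k in seq_len(dim(count)[4])) {
    for (i in seq_along(countries)) {
      gm <- matrix(gpop[i, ], nrow = dim(count)[1], ncol = dim(count)[3],
                   byrow = TRUE)
      count[, i, , k] <- samples$comp[, i, , k] * gm
    }
  }
  structure(list(count = count, pop = gpop, years = years,
                 countries = countries,
                 marital_group = samples$marital_group),
            class = "fp_counts")
}

#' Aggregation specification
#'
#' @param grouping one of `country`, `subregion`, `region`,
#'   `income_group`, `development_group`, `world`.
#' @param members named list mapping aggregate id to member country
#'   codes; must partition the country set (no overlaps).
#' @param min_obs suppression threshold: countries with fewer married
#'   any-method observations are not reported individually.
#' @param min_need ratio-suppression floor: groups whose median count of
#'   women in need falls below this are not reported for SDG 3.7.1.
#' @return list of class `aggregate_spec`.
#' @export
aggregate_spec <- function(grouping, members, min_obs = 2,
                           min_need = 1e5) {
  all_members <- unlist(members)
  if (anyDuplicated(all_members)) {
    stop("overlapping membership in grouping '", grouping, "': ",
         paste(unique(all_members[duplicated(all_members)]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(grouping = grouping, members = members,
                 min_obs = min_obs, min_need = min_need),
            class = "aggregate_spec")
}

# convenience: build the spec from a metadata column
spec_from_meta <- function(meta, grouping, ...) {
  members <- if (grouping == "world") {
    list(World = meta$country_code)
  } else {
    split(meta$country_code, meta[[grouping]])
  }
  aggregate_spec(grouping, members, ...)
}

#' Aggregate count draws over country groupings
#'
#' Sums the member countries' count draws (and populations) draw by draw,
#' producing the joint posterior of the aggregate. Aggregate proportions
#' are count-weighted by construction: summed numerator counts over
#' summed population.
#'
#' @param counts an `fp_counts` object.
#' @param spec an [aggregate_spec()].
#' @return `fp_counts` whose locations are the aggregate ids.
#' @export
aggregate_counts <- function(counts, spec) {
  missing_members <- setdiff(unlist(spec$members), counts$countries)
  if (length(missing_members)) {
    stop("member countries not present: ",
         paste(missing_members, collapse = ", "), call. = FALSE)
  }
  ids <- names(spec$members)
  dm <- dim(counts$count)
  agg <- array(0, c(dm[1], length(ids), dm[3], dm[4]),
               dimnames = list(NULL, ids, dimnames(counts$count)[[3]],
                               dimnames(counts$count)[[4]]))
  pop <- matrix(0, length(ids), dm[3], dimnames = list(ids, colnames(counts$pop)))
  for (j in seq_along(ids)) {
    idx <- match(spec$members[[j]], counts$countries)
    for (k in seq_len(dm[4])) {
      block <- counts$count[, idx, , k, drop = FALSE]
      agg[, j, , k] <- apply(block, c(1, 3), sum)
    }
    pop[j, ] <- colSums(counts$pop[idx, , drop = FALSE])
  }
  structure(list(count = agg, pop = pop, years = counts$years,
                 countries = ids, marital_group = counts$marital_group),
            class = "fp_counts")
}

#' Proportion draws implied by aggregated counts
#' @param counts an `fp_counts` object.
#' @return `fp_prop_samples` with comp = count / population.
#' @export
as_proportions <- function(counts) {
  comp <- counts$count
  for (k in seq_len(dim(comp)[4])) {
    for (i in seq_along(counts$countries)) {
      gm <- matrix(counts$pop[i, ], nrow = dim(comp)[1],
                   ncol = dim(comp)[3], byrow = TRUE)
      comp[, i, , k] <- ifelse(gm > 0, counts$count[, i, , k] / gm, 0)
    }
  }
  fp_prop(comp, counts$years, counts$countries, counts$marital_group)
}

#' Need satisfied by modern methods (SDG 3.7.1), per draw
#'
#' Modern-method use divided by total need (use of any method plus unmet
#' need), computed at the draw level. Draws with zero need give `NA`; a
#' location where every draw has zero need is suppressed downstream
#' rather than raising an error.
#'
#' @param x `fp_samples`, `fp_prop_samples` or `fp_counts`.
#' @return array `[draw, location, year]`.
#' @export
need_satisfied_modern <- function(x) {
  arr <- if (inherits(x, "fp_counts")) x$count else x$comp
  need <- arr[, , , 1, drop = FALSE] + arr[, , , 2, drop = FALSE] +
    arr[, , , 3, drop = FALSE]
  out <- ifelse(need > 0, arr[, , , 1, drop = FALSE] / need, NA_real_)
  array(out, dim = dim(arr)[1:3],
        dimnames = dimnames(arr)[1:3])
}

#' Summarise draws into estimate records
#'
#' Posterior medians and 95% uncertainty intervals (empirical 2.5th and
#' 97.5th percentiles) per location, year and indicator, followed by the
#' median-identity adjustment: the reported modern and traditional
#' medians are rescaled proportionally so that they sum to the reported
#' any-method median. Uncertainty intervals are never adjusted. Total
#' need is reported as the median of draw-level use + unmet; the need
#' identity is not forced at the median.
#'
#' @param x `fp_samples`, `fp_prop_samples` or `fp_counts`.
#' @param years subset of years to report (default: all).
#' @param min_draws minimum retained draws required (default 100).
#' @return data.frame of estimate records.
#' @export
summarize_draws <- function(x, years = NULL, min_draws = 100) {
  arr <- if (inherits(x, "fp_counts")) x$count else x$comp
  scale <- if (inherits(x, "fp_counts")) "count" else "proportion"
  if (dim(arr)[1] < min_draws) {
    stop("need at least ", min_draws, " retained draws", call. = FALSE)
  }
  yrs <- as.numeric(dimnames(arr)[[3]])
  y_idx <- if (is.null(years)) seq_along(yrs) else match(years, yrs)
  if (anyNA(y_idx)) stop("requested year outside the grid", call. = FALSE)
  locs <- dimnames(arr)[[2]]
  qs <- c(0.025, 0.5, 0.975)
  rows <- list()
  for (i in seq_along(locs)) {
    for (j in y_idx) {
      mod <- arr[, i, j, 1]; trad <- arr[, i, j, 2]
      unm <- arr[, i, j, 3]; non <- arr[, i, j, 4]
      any_d <- mod + trad
      need_d <- any_d + unm
      nsm_d <- ifelse(need_d > 0, mod / need_d, NA_real_)
      draws <- list(use_any = any_d, use_modern = mod,
                    use_traditional = trad, unmet = unm, need = need_d,
                    no_need = non, need_satisfied_modern = nsm_d)
      qv <- lapply(draws, function(d) {
        if (all(is.na(d))) c(NA_real_, NA_real_, NA_real_)
        else stats::quantile(d, qs, na.rm = TRUE, names = FALSE)
      })
      med <- vapply(qv, `[`, numeric(1), 2)
      # identity adjustment on the method-split medians only
      msum <- med[["use_modern"]] + med[["use_traditional"]]
      if (is.finite(msum) && msum > 0) {
        f <- med[["use_any"]] / msum
        med[["use_modern"]] <- med[["use_modern"]] * f
        med[["use_traditional"]] <- med[["use_traditional"]] * f
      }
      rows[[length(rows) + 1]] <- data.frame(
        location = locs[i], marital_group = x$marital_group,
        indicator = INDICATORS, scale = scale, year = yrs[j],
        median = unname(med[INDICATORS]),
        ui_low = vapply(qv, `[`, numeric(1), 1)[INDICATORS],
        ui_high = vapply(qv, `[`, numeric(1), 3)[INDICATORS],
        suppressed = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # the adjustment moves medians between the raw percentiles only by a
  # rounding-size amount; clamp into the interval to preserve ordering
  out$median <- pmin(pmax(out$median, out$ui_low), out$ui_high)
  out
}

#' Apply the reporting suppression rules
#'
#' Countries with fewer than `min_obs` (default two) survey observations
#' of married any-method prevalence are flagged suppressed for individual
#' reporting (they still contribute to aggregates, which are formed at
#' the draw level before summarising). SDG 3.7.1 ratio records are
#' flagged when the group's median count of women in need falls below
#' the configured floor.
#'
#' @param records estimate-record data.frame ([summarize_draws()]).
#' @param obs_counts country x marital-group observation count table from
#'   [validate_dataset()].
#' @param spec an [aggregate_spec()] carrying the thresholds.
#' @param need_medians optional named vector: median women-in-need count
#'   per location (count scale), used for the ratio rule.
#' @return `records` with the `suppressed` flag set.
#' @export
suppression_filter <- function(records, obs_counts, spec,
                               need_medians = NULL) {
  cn <- rownames(obs_counts)
  married_n <- obs_counts[, "married"]
  low <- cn[married_n < spec$min_obs]
  records$suppressed <- records$suppressed |
    (records$location %in% low)
  if (!is.null(need_medians)) {
    starved <- names(need_medians)[need_medians < spec$min_need]
    records$suppressed <- records$suppressed |
      (records$indicator == "need_satisfied_modern" &
         records$location %in% starved)
  }
  records
}

#' Adolescent share of all women of reproductive age
#'
#' Ratio of the adolescent (15-19) median count to the externally
#' supplied all-age (15-49) count per indicator category, in percent.
#' All-age counts are inputs, not estimated here.
#'
#' @param adolescent_records count-scale estimate records for ages 15-19.
#' @param all_age data.frame with columns `location`, `marital_group`,
#'   `indicator`, `count` (women 15-49).
#' @return data.frame with `location`, `marital_group`, `indicator`,
#'   `share_pct`, `suppressed` (zero denominators).
#' @export
adolescent_share <- function(adolescent_records, all_age) {
  if (is.null(all_age) || !nrow(all_age)) {
    stop("all-age (15-49) counts were not supplied; the adolescent ",
         "share is unavailable without them", call. = FALSE)
  }
  ado <- adolescent_records[adolescent_records$scale == "count", ]
  key <- function(d) paste(d$location, d$marital_group, d$indicator)
  idx <- match(key(ado), key(all_age))
  denom <- all_age$count[idx]
  share <- ifelse(!is.na(denom) & denom > 0,
                  100 * ado$median / denom, NA_real_)
  data.frame(location = ado$location, marital_group = ado$marital_group,
             indicator = ado$indicator, share_pct = share,
             suppressed = is.na(share), stringsAsFactors = FALSE)
}
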