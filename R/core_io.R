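# Readers, writers and dataset validation for the survey-observation,
# demography, metadata and results tables. All files are UTF-8 CSV with a
# header. Proportions are stored internally in [0, 1]; a file may carry
# percent-scale columns by suffixing the column name with `_pct`
# (e.g. `p_any_pct`), which are divided by 100 on read.

OBS_MANDATORY <- c("country_code", "marital_group", "ref_year", "source_type")
OBS_PROP_COLS <- c("p_any", "p_modern", "p_traditional", "p_unmet")
OBS_SE_COLS   <- c("se_any", "se_modern", "se_unmet")
OBS_FLAG_COLS <- c("baseline_flags", "misclass_flags")

parse_flags <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) character() else
    strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Read a survey-observation table
#'
#' One row per survey-based measurement of family planning indicators for
#' one country, reference year and marital group. Mandatory columns:
#' `country_code` (ISO alpha-3), `marital_group` (`married`/`unmarried`),
#' `ref_year` (decimal year, the fieldwork midpoint; whole-number calendar
#' years are mapped to year + 0.5), `source_type`. Optional:
#' the proportions `p_any`, `p_modern`, `p_traditional`, `p_unmet` (or
#' their `_pct` percent variants), standard errors `se_any`, `se_modern`,
#' `se_unmet`, and semicolon-separated `baseline_flags` and
#' `misclass_flags`. Unknown columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @return data.frame of class `fp_observations`.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # percent-convention columns
  for (col in c(OBS_PROP_COLS, OBS_SE_COLS)) {
    pct <- paste0(col, "_pct")
    if (pct %in% names(df)) {
      if (any(df[[pct]] < 0 | df[[pct]] > 100, na.rm = TRUE)) {
        stop("column ", pct, " outside [0, 100]", call. = FALSE)
      }
      df[[col]] <- df[[pct]] / 100
      df[[pct]] <- NULL
    }
  }
  missing_cols <- setdiff(OBS_MANDATORY, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  known <- c(OBS_MANDATORY, OBS_PROP_COLS, OBS_SE_COLS, OBS_FLAG_COLS)
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    df <- df[known[known %in% names(df)]]
  }
  for (col in setdiff(c(OBS_PROP_COLS, OBS_SE_COLS), names(df))) {
    df[[col]] <- NA_real_
  }
  for (col in setdiff(OBS_FLAG_COLS, names(df))) df[[col]] <- ""
  df$baseline_flags[is.na(df$baseline_flags)] <- ""
  df$misclass_flags[is.na(df$misclass_flags)] <- ""

  if (nrow(df)) {
    if (!all(df$marital_group %in% MARITAL_GROUPS)) {
      stop("marital_group must be one of: ",
           paste(MARITAL_GROUPS, collapse = ", "), call. = FALSE)
    }
    # whole-number reference years are calendar years: use the midpoint
    whole <- !is.na(df$ref_year) & df$ref_year == floor(df$ref_year)
    df$ref_year[whole] <- df$ref_year[whole] + 0.5
    validate_observation_rows(df)
  }
  df <- df[c(OBS_MANDATORY[1:3], OBS_PROP_COLS, OBS_MANDATORY[4],
             OBS_SE_COLS, OBS_FLAG_COLS)]
  class(df) <- c("fp_observations", "data.frame")
  df
}

validate_observation_rows <- function(df) {
  for (col in OBS_PROP_COLS) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad)) {
      stop("row ", bad[1], ": ", col, " outside [0, 1]", call. = FALSE)
    }
  }
  if (any(df$ref_year < 1960 | df$ref_year > 2030, na.rm = TRUE)) {
    stop("ref_year outside [1960, 2030]", call. = FALSE)
  }
  all3 <- !is.na(df$p_any) & !is.na(df$p_modern) & !is.na(df$p_traditional)
  gap <- abs(df$p_modern + df$p_traditional - df$p_any)
  bad <- which(all3 & gap > 0.005)
  if (length(bad)) {
    stop("row ", bad[1], ": p_modern + p_traditional differs from p_any ",
         "by more than 0.005", call. = FALSE)
  }
  flags_known <- list(baseline_flags = BASELINE_FLAGS,
                      misclass_flags = MISCLASS_FLAGS)
  for (col in names(flags_known)) {
    vals <- unique(unlist(lapply(df[[col]], parse_flags)))
    if (length(setdiff(vals, flags_known[[col]]))) {
      stop("unknown ", col, ": ",
           paste(setdiff(vals, flags_known[[col]]), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a demography table
#'
#' Long-format CSV with columns `country_code`, `year`, `pop_15_19`
#' (women aged 15-19, persons) and `prop_married` (in \[0, 1\]); optional
#' `pop_15_49`. Gaps within a country's observed year range are filled by
#' linear interpolation and years outside the range by constant extension;
#' filled rows are flagged in the `filled` column.
#'
#' @param path CSV file path.
#' @param years target annual grid (default 1970:2030).
#' @param interpolate fill gaps; if `FALSE`, a non-contiguous or
#'   incomplete series is an error.
#' @return data.frame of class `fp_demography` with one row per country
#'   and grid year.
#' @export
read_demography <- function(path, years = 1970:2030, interpolate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_code", "year", "pop_15_19", "prop_married")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$prop_married < 0 | df$prop_married > 1, na.rm = TRUE)) {
    stop("prop_married outside [0, 1]", call. = FALSE)
  }
  if (any(df$pop_15_19 < 0, na.rm = TRUE)) {
    stop("pop_15_19 must be >= 0", call. = FALSE)
  }
  has49 <- "pop_15_49" %in% names(df)
  out <- lapply(split(df, df$country_code), function(d) {
    d <- d[order(d$year), ]
    if (!interpolate &&
        !identical(as.integer(d$year), as.integer(years))) {
      stop("series for ", d$country_code[1],
           " does not cover the grid and interpolation is disabled",
           call. = FALSE)
    }
    fill <- function(v) {
      if (nrow(d) == 1) return(rep(v, length(years)))
      stats::approx(d$year, v, xout = years, rule = 2)$y
    }
    res <- data.frame(
      country_code = d$country_code[1], year = years,
      pop_15_19 = fill(d$pop_15_19),
      prop_married = fill(d$prop_married),
      filled = !(years %in% d$year)
    )
    if (has49) res$pop_15_49 <- fill(d$pop_15_49)
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fp_demography", "data.frame")
  res
}

#' Read the country metadata table
#'
#' Columns: `country_code`, `name`, `subregion`, `region`, and optionally
#' `income_group`, `development_group`, `activity_group` (0/1, may be NA
#' for married-only analyses).
#'
#' @param path CSV file path.
#' @return data.frame of class `fp_meta`.
#' @export
read_country_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_code", "name", "subregion", "region")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("income_group", "development_group")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!"activity_group" %in% names(df)) df$activity_group <- NA_integer_
  class(df) <- c("fp_meta", "data.frame")
  df
}

#' Cross-validate the three input tables
#'
#' Report-only: lists country codes present in observations or demography
#' but absent from the metadata (orphans), observations outside the year
#' grid, and per-country observation counts by marital group (the
#' any-method counts feed the suppression rule downstream).
#'
#' @param observations [read_observations()] output.
#' @param demography [read_demography()] output.
#' @param meta [read_country_meta()] output.
#' @return list of class `fp_validation` with `orphans`, `out_of_grid`,
#'   `obs_counts` (country x marital group, any-method observations),
#'   `issues` (character vector, empty when consistent).
#' @export
validate_dataset <- function(observations, demography, meta) {
  issues <- character()
  orphans <- sort(unique(c(
    setdiff(observations$country_code, meta$country_code),
    setdiff(demography$country_code, meta$country_code)
  )))
  if (length(orphans)) {
    issues <- c(issues, paste("orphan country codes:",
                              paste(orphans, collapse = ", ")))
  }
  no_demog <- setdiff(observations$country_code, demography$country_code)
  if (length(no_demog)) {
    issues <- c(issues, paste("countries without demography:",
                              paste(no_demog, collapse = ", ")))
  }
  grid <- range(demography$year)
  oog <- which(observations$ref_year < grid[1] |
                 observations$ref_year > grid[2] + 1)
  if (length(oog)) {
    issues <- c(issues, paste("observations outside the year grid, rows:",
                              paste(oog, collapse = ", ")))
  }
  has_any <- !is.na(observations$p_any)
  counts <- table(
    factor(observations$country_code[has_any], levels = meta$country_code),
    factor(observations$marital_group[has_any], levels = MARITAL_GROUPS)
  )
  structure(list(orphans = orphans, out_of_grid = oog,
                 obs_counts = counts, issues = issues),
            class = "fp_validation")
}

#' Write a validation report as JSON
#' @param report [validate_dataset()] output.
#' @param path output path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(orphans = report$orphans,
         out_of_grid = report$out_of_grid,
         obs_counts = as.data.frame(report$obs_counts,
                                    responseName = "n_obs"),
         issues = report$issues),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

ESTIMATE_COLS <- c("location", "marital_group", "indicator", "scale",
                   "year", "median", "ui_low", "ui_high", "suppressed")

#' Write and read estimate records
#'
#' Estimate records hold one summarised quantity per row: location
#' (country or aggregate), marital group (`married`/`unmarried`/`all`),
#' indicator, scale (`proportion`/`count`), year, posterior median, 95%
#' uncertainty interval, and the suppression flag. The round trip is exact
#' for text-representable values (written with full precision).
#'
#' @param records data.frame with the estimate-record columns.
#' @param path CSV file path.
#' @export
write_estimates <- function(records, path) {
  stopifnot(all(ESTIMATE_COLS %in% names(records)))
  bad <- with(records, which(!is.na(ui_low) & !is.na(ui_high) &
                               (ui_low > median | median > ui_high)))
  if (length(bad)) {
    stop("ui_low <= median <= ui_high violated at row ", bad[1],
         call. = FALSE)
  }
  out <- records[ESTIMATE_COLS]
  for (col in c("median", "ui_low", "ui_high")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE,
                   quote = which(vapply(out, is.character, logical(1))))
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("year", "median", "ui_low", "ui_high")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$suppressed <- as.logical(df$suppressed)
  df[ESTIMATE_COLS]
}
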