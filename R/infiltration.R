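# Outdoor-to-indoor infiltration factors F_inf = C_indoor,ambient / C_outdoor
# per microenvironment, pollutant and season. Open environments (walking,
# cycling) have F_inf = 1; enclosed environments attenuate (or, for some
# particle situations, can slightly exceed 1, hence the soft bound).

#' Reference infiltration-factor table
#'
#' Seasonal infiltration factors for PM2.5 and NO2 in every microenvironment,
#' as applied in the Hamburg study (literature-derived averages). Walking and
#' cycling are open-air and fixed at 1. The same values are used for the
#' aggregate `transport` environment of the plain dynamic approach (1 for both
#' pollutants and seasons).
#'
#' @return A tibble with columns `environment`, `pollutant` (`"PM2.5"`,
#'   `"NO2"`), `season` (`"winter"`, `"summer"`) and `finf`.
#' @export
default_infiltration_table <- function() {
  rows <- tibble::tribble(
    ~environment,      ~pm_w, ~pm_s, ~no2_w, ~no2_s,
    "home",            0.5,   0.6,   0.7,    0.8,
    "work",            0.5,   0.6,   0.75,   0.85,
    "other",           0.8,   1,     0.8,    1,
    "transport",       1,     1,     1,      1,
    "walking",         1,     1,     1,      1,
    "cycling",         1,     1,     1,      1,
    "in_car",          0.7,   0.8,   0.9,    0.9,
    "buses",           0.9,   0.9,   0.9,    0.9,
    "subway_trains",   0.7,   0.7,   0.6,    0.6,
    "suburban_trains", 0.7,   0.7,   0.7,    0.7,
    "regional_trains", 0.6,   0.6,   0.6,    0.6
  )
  rows |>
    tidyr::pivot_longer(-"environment", names_to = "key", values_to = "finf") |>
    dplyr::mutate(
      pollutant = ifelse(startsWith(.data$key, "pm"), "PM2.5", "NO2"),
      season = ifelse(endsWith(.data$key, "_w"), "winter", "summer")
    ) |>
    dplyr::select("environment", "pollutant", "season", "finf")
}

validate_infiltration_table <- function(table) {
  need <- c("environment", "pollutant", "season", "finf")
  if (!all(need %in% names(table))) {
    stop("infiltration table needs columns environment, pollutant, season, finf",
         call. = FALSE)
  }
  if (any(table$finf < 0 | table$finf > 1.5)) {
    stop("infiltration factors must lie in [0, 1.5]", call. = FALSE)
  }
  if (any(table$finf > 1)) {
    message("note: some infiltration factors exceed 1")
  }
  invisible(table)
}

#' Map a timestamp to the heating/non-heating season
#'
#' The seasonal split of the infiltration table defaults to winter =
#' October-March and summer = April-September (configurable via
#' `winter_months`). Under this default a leap year's 8784 hours split evenly,
#' 4392 per season.
#'
#' @param timestamp `POSIXct` vector (UTC).
#' @param winter_months Integer months counted as winter.
#' @return Character vector of `"winter"`/`"summer"`.
#' @export
season_of <- function(timestamp, winter_months = c(10:12, 1:3)) {
  m <- as.integer(format(timestamp, "%m", tz = "UTC"))
  ifelse(m %in% winter_months, "winter", "summer")
}

#' Resolve the infiltration factor for an environment at given times
#'
#' @param table Infiltration tibble, see [default_infiltration_table()].
#' @param env Environment id.
#' @param pollutant Pollutant name as used in the table.
#' @param timestamp `POSIXct` vector; the seasonal value for each instant's
#'   month is returned.
#' @param winter_months Passed to [season_of()].
#' @return Numeric vector of F_inf values, one per timestamp.
#' @export
resolve_finf <- function(table, env, pollutant, timestamp,
                         winter_months = c(10:12, 1:3)) {
  season <- season_of(timestamp, winter_months)
  sub <- table[table$environment == env & table$pollutant == pollutant, , drop = FALSE]
  idx <- match(season, sub$season)
  if (anyNA(idx)) {
    miss <- unique(season[is.na(idx)])
    stop(sprintf("no infiltration factor for (%s, %s, %s)",
                 env, pollutant, paste(miss, collapse = "/")), call. = FALSE)
  }
  sub$finf[idx]
}

#' Scenario variants of an infiltration table
#'
#' Builds the `{reference, minimum, maximum}` variant set used by the
#' sensitivity machinery. When no measured variant tables are supplied, the
#' minimum and maximum are generated as `reference * (1 -/+ fraction)` for the
#' selected environments (by default the transport modes, whose in-cabin
#' factors carry the largest uncertainty), with the maximum capped at the
#' table's admissible bound of 1.5.
#'
#' @param reference Reference infiltration tibble.
#' @param fraction Relative half-width of the generated band (default 0.2).
#' @param environments Environments whose factors vary; others keep the
#'   reference value in all variants.
#' @return A named list of three infiltration tibbles.
#' @export
infiltration_scenarios <- function(reference = default_infiltration_table(),
                                   fraction = 0.2,
                                   environments = transport_modes()) {
  validate_infiltration_table(reference)
  vary <- reference$environment %in% environments
  minimum <- maximum <- reference
  minimum$finf[vary] <- reference$finf[vary] * (1 - fraction)
  maximum$finf[vary] <- pmin(reference$finf[vary] * (1 + fraction), 1.5)
  list(reference = reference, minimum = minimum, maximum = maximum)
}

#' Scale every infiltration factor by a common factor
#'
#' Useful for linearity checks: with concentrations and populations held
#' fixed, scaling all F_inf by `alpha` scales every per-environment exposure
#' by exactly `alpha`.
#'
#' @param table Infiltration tibble.
#' @param alpha Positive scale factor.
#' @return The scaled tibble.
#' @export
scale_finf <- function(table, alpha) {
  stopifnot(alpha > 0)
  table$finf <- table$finf * alpha
  table
}

#' Read/write infiltration tables as CSV
#'
#' Plain CSV with columns `environment,pollutant,season,finf`.
#'
#' @param path File path.
#' @param table Infiltration tibble.
#' @export
read_infiltration_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  validate_infiltration_table(tb)
  tb
}

#' @rdname read_infiltration_csv
#' @export
write_infiltration_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
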