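# Model-vs-observation evaluation statistics as used for urban dispersion
# model benchmarking: mean bias, normalized mean bias (sum-ratio form),
# RMSE, Pearson r, Willmott index of agreement, and the fraction of pairs
# within a factor of two, with the FAIRMODE FAC2 >= 0.3 acceptance check.

#' Evaluation statistics for paired observed/modelled series
#'
#' Pairs with a missing value on either side are excluded before anything is
#' computed. Definitions (over the n valid pairs, d = mod - obs):
#' * `MB   = mean(d)`
#' * `NMB  = sum(d) / sum(obs)` (equivalent to `MB / mean(obs)`)
#' * `RMSE = sqrt(mean(d^2))`
#' * `r`    = Pearson correlation (`NA` for a constant series, never 0)
#' * `IOA  = 1 - sum(d^2) / sum((|mod - mean(obs)| + |obs - mean(obs)|)^2)`
#'   (the classical Willmott index)
#' * `FAC2` = fraction of pairs with `0.5 <= mod/obs <= 2`; pairs with
#'   `obs == 0` are excluded from this ratio count (standard convention,
#'   reported via a message).
#'
#' @param data A data frame with the paired series.
#' @param observed,modelled Column names (strings) of the observed and
#'   modelled concentrations.
#' @return A one-row tibble: `n`, `FAC2`, `MB`, `NMB`, `RMSE`, `r`, `IOA`.
#' @examples
#' evaluate_model(data.frame(obs = c(1, 2, 3), mod = c(2, 3, 4)), "obs", "mod")
#' @export
evaluate_model <- function(data, observed = "observed", modelled = "modelled") {
  obs <- data[[observed]]
  mod <- data[[modelled]]
  ok <- is.finite(obs) & is.finite(mod)
  obs <- obs[ok]
  mod <- mod[ok]
  n <- length(obs)
  if (n < 2) stop("need at least 2 valid pairs", call. = FALSE)
  d <- mod - obs
  mb <- mean(d)
  nmb <- sum(d) / sum(obs)
  rmse <- sqrt(mean(d^2))
  r <- if (stats::sd(obs) == 0 || stats::sd(mod) == 0) NA_real_ else
    stats::cor(obs, mod)
  denom <- sum((abs(mod - mean(obs)) + abs(obs - mean(obs)))^2)
  ioa <- if (denom == 0) NA_real_ else 1 - sum(d^2) / denom
  nz <- obs != 0
  if (any(!nz)) {
    message(sprintf("FAC2: excluded %d pair(s) with observed == 0", sum(!nz)))
  }
  ratio <- mod[nz] / obs[nz]
  fac2 <- if (any(nz)) mean(ratio >= 0.5 & ratio <= 2) else NA_real_
  tibble::tibble(n = n, FAC2 = fac2, MB = mb, NMB = nmb, RMSE = rmse,
                 r = r, IOA = ioa)
}

#' FAIRMODE FAC2 acceptance check
#'
#' Passes iff `fac2 >= 0.3` (boundary inclusive), the acceptance criterion
#' for urban dispersion model evaluation.
#'
#' @param fac2 A FAC2 fraction in `[0, 1]`.
#' @return `TRUE`/`FALSE`.
#' @export
fairmode_fac2_check <- function(fac2) {
  if (!is.numeric(fac2) || is.na(fac2) || fac2 < 0 || fac2 > 1) {
    stop("`fac2` must be a fraction in [0, 1]", call. = FALSE)
  }
  fac2 >= 0.3
}

#' Aggregate an hourly series to daily means with a coverage requirement
#'
#' Convenience for pollutants evaluated on daily means (e.g. PM2.5) while the
#' model output is hourly: days with less than the required fraction of valid
#' hours are dropped.
#'
#' @param data Data frame with a `POSIXct` time column and a value column.
#' @param time,value Column names (strings).
#' @param min_coverage Minimum fraction of valid hours per day (default 0.75).
#' @return A tibble with columns `date`, `value` (daily mean), `n_hours`.
#' @export
daily_means <- function(data, time = "time", value = "value", min_coverage = 0.75) {
  tb <- tibble::tibble(
    date = as.Date(data[[time]], tz = "UTC"),
    v = data[[value]]
  )
  tb |>
    dplyr::summarise(
      value = mean(.data$v[is.finite(.data$v)]),
      n_hours = sum(is.finite(.data$v)),
      .by = "date"
    ) |>
    dplyr::filter(.data$n_hours >= min_coverage * 24) |>
    dplyr::select("date", "value", "n_hours")
}
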