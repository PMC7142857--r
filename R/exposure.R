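# Exposure metrics. Per cell i, environment j and hour t:
#
#   E_i      = sum_j F_inf,j(t) * sum_t C_{i,t} * P_{i,j,t}      (total exposure)
#   PWE_i    = E_i / sum_j sum_t P_{i,j,t}                        (person-hour weighted)
#
# with F_inf resolved per season of t. Total exposure is reported in
# ug/m3 * persons summed over hours (the hour weighting is implicit in the
# sum); PWE is in ug/m3 — the average concentration the population actually
# experiences. Summation order is fixed (time innermost) so domain totals are
# bit-reproducible.

#' Point exposure: concentration x population x infiltration
#'
#' @param concentration Ambient concentration (ug/m3).
#' @param population Exposed persons (>= 0).
#' @param finf Infiltration factor.
#' @return `concentration * population * finf`, vectorized.
#' @export
cell_exposure <- function(concentration, population, finf = 1) {
  if (!all(is.finite(concentration)) || !all(is.finite(population)) ||
      !all(is.finite(finf))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(population < 0)) stop("population must be >= 0", call. = FALSE)
  concentration * population * finf
}

#' Total exposure per cell and microenvironment
#'
#' Applies the hour-summed exposure formula over a concentration stack and
#' per-environment population stacks sharing the same grid and time axis.
#'
#' @param conc [hourly_stack()] of concentrations (ug/m3).
#' @param pop Named list of [hourly_stack()]s of persons, one per environment
#'   (e.g. from [build_hourly_population()]).
#' @param finf_table Infiltration tibble, see [default_infiltration_table()];
#'   pass `NULL` to expose to raw ambient concentrations (F = 1 everywhere).
#' @param pollutant Pollutant name used for the infiltration lookup.
#' @param approach Label stored with the result.
#' @return An `exposure_result`: per-environment per-cell exposure matrices
#'   (`$envs`), a tidy totals tibble (`$totals`), grid, pollutant, approach.
#' @export
total_exposure <- function(conc, pop, finf_table = default_infiltration_table(),
                           pollutant = "NO2", approach = "dynamic") {
  stopifnot(inherits(conc, "hourly_stack"), is.list(pop), length(pop) > 0)
  envs <- names(pop)
  if (is.null(envs) || any(!nzchar(envs))) {
    stop("`pop` must be a named list of environment stacks", call. = FALSE)
  }
  nt <- length(conc$times)
  mats <- vector("list", length(envs))
  names(mats) <- envs
  for (env in envs) {
    check_alignment(conc, pop[[env]], sprintf("concentration and '%s' population", env))
    f <- if (is.null(finf_table)) rep(1, nt) else
      resolve_finf(finf_table, env, pollutant, conc$times)
    acc <- matrix(0, nrow = conc$grid$n_y, ncol = conc$grid$n_x)
    for (t in seq_len(nt)) { # time innermost, fixed order
      acc <- acc + f[t] * conc$values[t, , ] * pop[[env]]$values[t, , ]
    }
    mats[[env]] <- acc
  }
  totals <- tibble::tibble(
    environment = envs,
    exposure = unname(vapply(mats, sum, numeric(1))),
    pollutant = pollutant,
    approach = approach
  )
  structure(
    list(grid = conc$grid, envs = mats, totals = totals, pollutant = pollutant,
         approach = approach, times = conc$times),
    class = "exposure_result"
  )
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("<exposure_result> %s, %s approach, %d hours\n",
              x$pollutant, x$approach, length(x$times)))
  print(x$totals)
  invisible(x)
}

#' Tidy methods for exposure results
#'
#' `tidy()` returns the per-environment totals tibble; `glance()` a one-row
#' summary.
#'
#' @param x An `exposure_result`.
#' @param ... Unused.
#' @export
tidy.exposure_result <- function(x, ...) x$totals

#' @rdname tidy.exposure_result
#' @export
glance.exposure_result <- function(x, ...) {
  tibble::tibble(
    pollutant = x$pollutant, approach = x$approach,
    n_environments = length(x$envs), n_hours = length(x$times),
    total_exposure = sum(x$totals$exposure)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Population-weighted exposure
#'
#' Total exposure divided by cumulative person-hours: the average (possibly
#' infiltration-attenuated) concentration experienced by the population in
#' the chosen scope. Computed per environment and aggregated over the scope;
#' person-hour weighting is always used for aggregates. Environments with
#' zero cumulative population report `NA` with a warning — an empty
#' environment has no defined PWE, not a PWE of 0.
#'
#' @inheritParams total_exposure
#' @param scope Environments to include: `"all"` (default) or a character
#'   vector of environment ids present in `pop`.
#' @param per_cell Also return the per-cell PWE raster for the scope?
#' @return A `pwe_result` with `$by_environment` (tibble: environment,
#'   exposure, person_hours, pwe), `$pwe` (scope-aggregate, ug/m3) and
#'   optionally `$per_cell`.
#' @export
population_weighted_exposure <- function(conc, pop,
                                         finf_table = default_infiltration_table(),
                                         pollutant = "NO2", scope = "all",
                                         per_cell = FALSE, approach = "dynamic") {
  if (identical(scope, "all")) scope <- names(pop)
  missing_envs <- setdiff(scope, names(pop))
  if (length(missing_envs) > 0) {
    stop(sprintf("scope environments not in `pop`: %s",
                 paste(missing_envs, collapse = ", ")), call. = FALSE)
  }
  exp_res <- total_exposure(conc, pop[scope], finf_table, pollutant, approach)
  ph <- lapply(scope, function(env) {
    acc <- matrix(0, nrow = conc$grid$n_y, ncol = conc$grid$n_x)
    for (t in seq_along(conc$times)) acc <- acc + pop[[env]]$values[t, , ]
    acc
  })
  names(ph) <- scope
  ph_tot <- unname(vapply(ph, sum, numeric(1)))
  e_tot <- exp_res$totals$exposure
  pwe_env <- ifelse(ph_tot > 0, e_tot / ph_tot, NA_real_)
  if (any(ph_tot == 0)) {
    warning(sprintf("zero cumulative population in: %s; PWE undefined there",
                    paste(scope[ph_tot == 0], collapse = ", ")), call. = FALSE)
  }
  by_env <- tibble::tibble(
    environment = scope, exposure = e_tot, person_hours = ph_tot,
    pwe = pwe_env, pollutant = pollutant, approach = approach
  )
  num <- Reduce(`+`, exp_res$envs)
  den <- Reduce(`+`, ph)
  out <- list(
    by_environment = by_env,
    pwe = if (sum(den) > 0) sum(num) / sum(den) else NA_real_,
    person_hours = sum(den), scope = scope,
    pollutant = pollutant, approach = approach
  )
  if (per_cell) {
    vals <- ifelse(den > 0, num / den, NA_real_)
    out$per_cell <- raster_field(conc$grid, vals, units = "ug/m3", name = "PWE")
  }
  structure(out, class = "pwe_result")
}

#' @export
print.pwe_result <- function(x, ...) {
  cat(sprintf("<pwe_result> %s, %s approach, scope aggregate %.4g ug/m3\n",
              x$pollutant, x$approach, x$pwe))
  print(x$by_environment)
  invisible(x)
}

#' @export
tidy.pwe_result <- function(x, ...) x$by_environment

#' @export
glance.pwe_result <- function(x, ...) {
  tibble::tibble(pollutant = x$pollutant, approach = x$approach,
                 pwe = x$pwe, person_hours = x$person_hours,
                 n_environments = length(x$scope))
}

#' Source contribution via zero-out differencing
#'
#' The contribution of a source (e.g. road traffic) is the difference between
#' the full concentration field and a zero-out field computed without that
#' source. The exposure contribution is the exposure of the difference field;
#' the relative contribution divides it by the full-field exposure.
#' Differenced fields may be locally negative (chemistry); negative values
#' propagate and are never clipped, but more than 1% of negative cell-hours
#' triggers a warning.
#'
#' @param conc_full,conc_zero_out Aligned [hourly_stack()]s with and without
#'   the source.
#' @inheritParams total_exposure
#' @return A `contribution_result` with per-environment tibble
#'   (`$by_environment`: exposure_full, contribution, relative) and per-cell
#'   contribution matrices (`$envs`).
#' @export
source_contribution <- function(conc_full, conc_zero_out, pop,
                                finf_table = default_infiltration_table(),
                                pollutant = "NO2", approach = "dynamic") {
  check_alignment(conc_full, conc_zero_out, "full and zero-out stacks")
  neg <- mean(conc_zero_out$values > conc_full$values)
  if (neg > 0.01) {
    warning(sprintf("zero-out exceeds the full field in %.1f%% of cell-hours",
                    100 * neg), call. = FALSE)
  }
  diff_stack <- hourly_stack(conc_full$grid, conc_full$times,
                             conc_full$values - conc_zero_out$values,
                             units = conc_full$units)
  e_full <- total_exposure(conc_full, pop, finf_table, pollutant, approach)
  e_diff <- total_exposure(diff_stack, pop, finf_table, pollutant, approach)
  by_env <- tibble::tibble(
    environment = e_full$totals$environment,
    exposure_full = e_full$totals$exposure,
    contribution = e_diff$totals$exposure,
    relative = ifelse(e_full$totals$exposure != 0,
                      e_diff$totals$exposure / e_full$totals$exposure, NA_real_),
    pollutant = pollutant, approach = approach
  )
  structure(
    list(by_environment = by_env, envs = e_diff$envs, envs_full = e_full$envs,
         grid = conc_full$grid, pollutant = pollutant, approach = approach),
    class = "contribution_result"
  )
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("<contribution_result> %s, %s approach\n", x$pollutant, x$approach))
  print(x$by_environment)
  invisible(x)
}

#' @export
tidy.contribution_result <- function(x, ...) x$by_environment

#' Per-environment shares of an exposure total
#'
#' Fractions of the scope total contributed by each environment, summing
#' to 1. Use `scope = "transport_modes"` for the share of each mode within
#' the transport environment.
#'
#' @param result An `exposure_result`.
#' @param scope `"all"`, `"transport_modes"`, or a character vector of
#'   environment ids.
#' @return A tibble with columns `environment` and `share`, or shares `NA`
#'   (with a warning) when the scope total is zero.
#' @export
environment_shares <- function(result, scope = "all") {
  stopifnot(inherits(result, "exposure_result"))
  envs <- if (identical(scope, "all")) result$totals$environment
          else if (identical(scope, "transport_modes"))
            intersect(transport_modes(), result$totals$environment)
          else scope
  sub <- result$totals[result$totals$environment %in% envs, , drop = FALSE]
  total <- sum(sub$exposure)
  if (total == 0) {
    warning("zero scope total; shares undefined", call. = FALSE)
    return(tibble::tibble(environment = sub$environment, share = NA_real_))
  }
  tibble::tibble(environment = sub$environment, share = sub$exposure / total)
}
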