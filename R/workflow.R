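# End-to-end orchestration: build masks for a city, run one approach over a
# concentration stack, and run sensitivity scenario matrices over emission-
# driven concentration variants and infiltration variants.

#' Build all environment masks for a city
#'
#' Combines the four base-environment masks (from land-use polygons) and the
#' seven transport-mode masks (from the tagged network) into one mask set.
#' The land-use based `transport` mask and the polyline-based mode masks stay
#' distinct: the dynamic approach uses the former, the dynamic transport
#' approach the latter.
#'
#' @param city A [generate_city()] result, or any list with `lulc`,
#'   `network` and `grid` of the same shapes.
#' @param mapping Land-use mapping, see [default_lulc_mapping()].
#' @param queries Mode tag queries, see [default_mode_queries()].
#' @return An `env_mask_set` with 11 masks.
#' @export
build_city_masks <- function(city, mapping = default_lulc_mapping(),
                             queries = default_mode_queries()) {
  base <- build_base_environments(city$lulc, mapping, city$grid)
  modes <- build_transport_environments(city$network, queries, city$grid)
  structure(c(base, modes), grid = city$grid, class = "env_mask_set")
}

#' Run one exposure approach end to end
#'
#' Builds the hourly population for the approach, computes total exposure,
#' population-weighted exposure and environment shares, and — when a zero-out
#' concentration stack is supplied — the road-traffic (or other source)
#' contribution. Deterministic given its inputs.
#'
#' @param conc Concentration [hourly_stack()].
#' @param masks An `env_mask_set` covering the approach's environments.
#' @param inventory A [population_inventory()].
#' @param approach `"static"`, `"dynamic"` or `"dynamic_transport"`.
#' @param pollutant Pollutant name for infiltration lookup.
#' @param profile Activity profiles, see [default_activity_profiles()].
#' @param commuters A [commuter_spec()] or `NULL`.
#' @param split Modal split for `dynamic_transport`.
#' @param finf_table Infiltration table; `NULL` disables infiltration (F = 1).
#' @param conc_zero_out Optional aligned zero-out stack.
#' @param output_dir Optional directory; when given, tidy CSV summaries,
#'   per-environment exposure rasters and a run manifest are written there.
#' @return A list: `exposure` (`exposure_result`), `pwe` (`pwe_result`),
#'   `shares` (tibble), `contribution` (`contribution_result` or `NULL`),
#'   `population` (the hourly stacks).
#' @export
run_exposure <- function(conc, masks, inventory,
                         approach = c("dynamic_transport", "dynamic", "static"),
                         pollutant = "NO2",
                         profile = default_activity_profiles(),
                         commuters = NULL, split = hamburg_modal_split(),
                         finf_table = default_infiltration_table(),
                         conc_zero_out = NULL, output_dir = NULL) {
  approach <- match.arg(approach)
  pop <- build_hourly_population(inventory, profile, commuters, split, masks,
                                 approach, conc$times)
  exposure <- total_exposure(conc, pop, finf_table, pollutant, approach)
  pwe <- population_weighted_exposure(conc, pop, finf_table, pollutant,
                                      scope = "all", approach = approach)
  shares <- environment_shares(exposure, scope = "all")
  contribution <- if (!is.null(conc_zero_out)) {
    source_contribution(conc, conc_zero_out, pop, finf_table, pollutant, approach)
  }
  out <- list(exposure = exposure, pwe = pwe, shares = shares,
              contribution = contribution, population = pop,
              approach = approach, pollutant = pollutant)
  if (!is.null(output_dir)) write_run_outputs(out, output_dir)
  out
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary_tbl <- run$exposure$totals |>
    dplyr::left_join(run$shares, by = "environment") |>
    dplyr::left_join(
      run$pwe$by_environment |> dplyr::select("environment", "person_hours", "pwe"),
      by = "environment"
    )
  readr::write_csv(summary_tbl, file.path(dir, "exposure_summary.csv"))
  for (env in names(run$exposure$envs)) {
    write_raster_csv(
      raster_field(run$exposure$grid, run$exposure$envs[[env]],
                   units = "ug/m3*persons", name = env),
      file.path(dir, sprintf("exposure_%s.csv", env))
    )
  }
  if (!is.null(run$contribution)) {
    readr::write_csv(run$contribution$by_environment,
                     file.path(dir, "source_contribution.csv"))
  }
  yaml::write_yaml(
    list(approach = run$approach, pollutant = run$pollutant,
         n_hours = length(run$exposure$times),
         environments = names(run$exposure$envs),
         package_version = as.character(utils::packageVersion("tmaexposure"))),
    file.path(dir, "manifest.yaml")
  )
  invisible(dir)
}

#' Run a sensitivity scenario matrix
#'
#' Each scenario pairs a concentration stack (an emission-driven variant)
#' with an infiltration table. The report gives, per environment, the
#' relative change of total exposure and PWE against the `reference`
#' scenario, in percent. A scenario identical to the reference reports 0%
#' exactly; an environment with zero reference exposure reports `NA`.
#'
#' @param scenarios Named list of scenarios, each
#'   `list(conc = <hourly_stack>, finf = <infiltration tibble>)`; must
#'   contain one named `reference`.
#' @inheritParams run_exposure
#' @return A `sensitivity_report` tibble: `scenario`, `environment`,
#'   `pollutant`, `total_exposure`, `pwe`, `exposure_change_pct`,
#'   `pwe_change_pct`.
#' @export
run_sensitivity <- function(scenarios, masks, inventory,
                            approach = "dynamic_transport", pollutant = "NO2",
                            profile = default_activity_profiles(),
                            commuters = NULL, split = hamburg_modal_split()) {
  if (!"reference" %in% names(scenarios)) {
    stop("`scenarios` must contain a 'reference' entry", call. = FALSE)
  }
  # the population does not vary across scenarios; build it once
  times <- scenarios$reference$conc$times
  pop <- build_hourly_population(inventory, profile, commuters, split, masks,
                                 approach, times)
  one <- function(sc, name) {
    ex <- total_exposure(sc$conc, pop, sc$finf, pollutant, approach)
    pw <- population_weighted_exposure(sc$conc, pop, sc$finf, pollutant,
                                       scope = "all", approach = approach)
    ex$totals |>
      dplyr::select("environment", total_exposure = "exposure") |>
      dplyr::left_join(pw$by_environment |> dplyr::select("environment", "pwe"),
                       by = "environment") |>
      dplyr::mutate(scenario = name, pollutant = pollutant)
  }
  rows <- purrr::imap(scenarios, one) |> dplyr::bind_rows()
  ref <- rows |>
    dplyr::filter(.data$scenario == "reference") |>
    dplyr::select("environment", ref_exposure = "total_exposure", ref_pwe = "pwe")
  out <- rows |>
    dplyr::left_join(ref, by = "environment") |>
    dplyr::mutate(
      exposure_change_pct = ifelse(.data$ref_exposure != 0,
                                   (.data$total_exposure / .data$ref_exposure - 1) * 100,
                                   NA_real_),
      pwe_change_pct = ifelse(is.finite(.data$ref_pwe) & .data$ref_pwe != 0,
                              (.data$pwe / .data$ref_pwe - 1) * 100, NA_real_)
    ) |>
    dplyr::select("scenario", "environment", "pollutant", "total_exposure",
                  "pwe", "exposure_change_pct", "pwe_change_pct")
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Assemble the standard emission/infiltration scenario matrix for a city
#'
#' Builds the `{reference, minimum, maximum}` matrix the sensitivity analysis
#' runs: concentration variants are generated with the city's road increment
#' scaled by the per-pollutant emission factors (minimum = the unscaled
#' original inventory relative to the reference rescaling, maximum = the
#' upper rescaling), combined with the matching infiltration variants.
#'
#' @param city A [generate_city()] result.
#' @param times Hourly `POSIXct` axis.
#' @param pollutant Pollutant to build stacks for.
#' @param emission_factors Named numeric factors relative to the reference,
#'   e.g. `c(reference = 1, minimum = 1/1.3, maximum = 1.4/1.3)` for NO2
#'   (the reference inventory carries a x1.3 rescaling; the minimum is the
#'   original inventory, the maximum a x1.4 rescaling).
#' @param finf_variants Output of [infiltration_scenarios()].
#' @return A named scenario list suitable for [run_sensitivity()].
#' @export
city_scenarios <- function(city, times, pollutant = "NO2",
                           emission_factors = c(reference = 1,
                                                minimum = 1 / 1.3,
                                                maximum = 1.4 / 1.3),
                           finf_variants = infiltration_scenarios()) {
  stopifnot(all(c("reference", "minimum", "maximum") %in% names(emission_factors)))
  finf_key <- c(reference = "reference", minimum = "minimum", maximum = "maximum")
  out <- lapply(names(emission_factors), function(nm) {
    fields <- generate_concentration_fields(city, times, emission_factors[[nm]])
    list(conc = fields[[pollutant]]$full, finf = finf_variants[[finf_key[[nm]]]])
  })
  names(out) <- names(emission_factors)
  out
}
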