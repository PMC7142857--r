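# Hourly population fields P_{i,j,t}: the temporal dynamics come from diurnal
# activity profiles (share of the total population in each base environment
# per hour and day type) plus scheduled commuters; the spatial dynamics come
# from distributing each environment's hourly total over its mask.

#' Generic diurnal activity profiles
#'
#' Hourly fractions of the total population in the four base environments for
#' weekdays and weekends. Every hourly row sums to 1. The shipped values are a
#' plausible generic European urban pattern (nights at home, a broad working
#' day, rush-hour transport peaks, more leisure time on weekends); they are
#' **non-authoritative defaults** — city-specific profiles should be supplied
#' whenever available, as a tibble of the same shape.
#'
#' @return A tibble with columns `day_type` (`weekday`/`weekend`), `hour`
#'   (0-23), `environment` (base ids) and `fraction`.
#' @export
default_activity_profiles <- function() {
  wd <- rbind(
    matrix(rep(c(0.97, 0.01, 0.01, 0.01), 5), ncol = 4, byrow = TRUE), # 0-4
    c(0.94, 0.02, 0.02, 0.02),                                          # 5
    c(0.85, 0.06, 0.04, 0.05),                                          # 6
    c(0.68, 0.14, 0.08, 0.10),                                          # 7
    c(0.52, 0.28, 0.10, 0.10),                                          # 8
    c(0.42, 0.40, 0.13, 0.05),                                          # 9
    matrix(rep(c(0.40, 0.40, 0.15, 0.05), 5), ncol = 4, byrow = TRUE),  # 10-14
    c(0.42, 0.38, 0.14, 0.06),                                          # 15
    c(0.46, 0.32, 0.14, 0.08),                                          # 16
    c(0.52, 0.24, 0.14, 0.10),                                          # 17
    c(0.62, 0.16, 0.14, 0.08),                                          # 18
    c(0.72, 0.10, 0.13, 0.05),                                          # 19
    c(0.81, 0.06, 0.10, 0.03),                                          # 20
    c(0.88, 0.03, 0.07, 0.02),                                          # 21
    c(0.93, 0.02, 0.03, 0.02),                                          # 22
    c(0.96, 0.01, 0.02, 0.01)                                           # 23
  )
  we <- rbind(
    matrix(rep(c(0.97, 0.01, 0.01, 0.01), 7), ncol = 4, byrow = TRUE), # 0-6
    c(0.92, 0.01, 0.04, 0.03),                                          # 7
    c(0.84, 0.02, 0.09, 0.05),                                          # 8
    c(0.74, 0.03, 0.16, 0.07),                                          # 9
    c(0.64, 0.04, 0.24, 0.08),                                          # 10
    matrix(rep(c(0.58, 0.04, 0.30, 0.08), 6), ncol = 4, byrow = TRUE),  # 11-16
    c(0.64, 0.04, 0.25, 0.07),                                          # 17
    c(0.72, 0.03, 0.19, 0.06),                                          # 18
    c(0.80, 0.02, 0.14, 0.04),                                          # 19
    c(0.86, 0.02, 0.09, 0.03),                                          # 20
    c(0.91, 0.01, 0.06, 0.02),                                          # 21
    c(0.95, 0.01, 0.03, 0.01),                                          # 22
    c(0.97, 0.01, 0.01, 0.01)                                           # 23
  )
  tidy_one <- function(m, day_type) {
    colnames(m) <- base_environments()
    tibble::as_tibble(m) |>
      dplyr::mutate(hour = 0:23, day_type = day_type) |>
      tidyr::pivot_longer(dplyr::all_of(base_environments()),
                          names_to = "environment", values_to = "fraction")
  }
  out <- dplyr::bind_rows(tidy_one(wd, "weekday"), tidy_one(we, "weekend"))
  out[, c("day_type", "hour", "environment", "fraction")]
}

#' @rdname default_activity_profiles
#' @param profile An activity-profile tibble to validate.
#' @export
validate_activity_profile <- function(profile) {
  need <- c("day_type", "hour", "environment", "fraction")
  if (!all(need %in% names(profile))) {
    stop("profile must have columns day_type, hour, environment, fraction", call. = FALSE)
  }
  if (any(profile$fraction < 0 | profile$fraction > 1)) {
    stop("profile fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- profile |>
    dplyr::summarise(s = sum(.data$fraction), .by = c("day_type", "hour"))
  bad <- sums[abs(sums$s - 1) > 1e-9, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop(sprintf("profile rows not summing to 1: %s",
                 paste(sprintf("%s h%02d (%.12f)", bad$day_type, bad$hour, bad$s),
                       collapse = "; ")), call. = FALSE)
  }
  invisible(profile)
}

#' Modal split over the seven transport modes
#'
#' `hamburg_modal_split()` returns the printed average split for the Hamburg
#' urban area: 27% walking, 15% cycling, 36% car, 22% public transport, with
#' the public-transport share subdivided 36% bus, 32% subway, 25% suburban
#' trains, 6% regional trains and 1% ferries. The neglected ferry share is
#' dropped and the remaining public-transport sub-shares renormalized, so the
#' seven mode fractions sum to 1.
#'
#' @return A tibble with columns `mode` and `fraction`.
#' @export
hamburg_modal_split <- function() {
  pt <- 0.22
  sub <- c(buses = 0.36, subway_trains = 0.32,
           suburban_trains = 0.25, regional_trains = 0.06)
  sub <- sub / sum(sub) # drop the 1% ferry share, renormalize
  tibble::tibble(
    mode = transport_modes(),
    fraction = c(0.27, 0.15, 0.36, unname(pt * sub[transport_modes()[4:7]]))
  )
}

validate_modal_split <- function(split) {
  if (!all(c("mode", "fraction") %in% names(split))) {
    stop("modal split needs columns `mode` and `fraction`", call. = FALSE)
  }
  if (any(split$fraction < 0)) stop("modal-split fractions must be >= 0", call. = FALSE)
  if (abs(sum(split$fraction) - 1) > 1e-9) {
    stop(sprintf("modal-split fractions sum to %.12f, expected 1", sum(split$fraction)),
         call. = FALSE)
  }
  invisible(split)
}

#' Commuter schedule
#'
#' Commuters enter the domain on workdays only: they are assigned to the
#' transport environment(s) during rush-hour windows and to the work
#' environment during working hours. Window bounds are hours of day,
#' half-open `[from, to)`.
#'
#' @param count Daily commuter count (persons), e.g. 223000 for Hamburg.
#' @param rush_windows List of `c(from, to)` hour pairs. Defaults to
#'   07:00-09:00 and 16:00-19:00.
#' @param work_hours `c(from, to)` working-hour window, default 09:00-16:00.
#' @param workday_only Apply on Mon-Fri only (default `TRUE`).
#' @return A `commuter_spec` list.
#' @export
commuter_spec <- function(count = 0,
                          rush_windows = list(c(7, 9), c(16, 19)),
                          work_hours = c(9, 16),
                          workday_only = TRUE) {
  stopifnot(count >= 0)
  for (w in rush_windows) {
    stopifnot(length(w) == 2, w[1] >= 0, w[2] <= 24, w[1] < w[2])
  }
  structure(list(count = count, rush_windows = rush_windows,
                 work_hours = work_hours, workday_only = workday_only),
            class = "commuter_spec")
}

#' Residential population inventory
#'
#' Couples the rasterized residential population with a growth factor that
#' rescales the (older) census total to the study year; the Hamburg
#' application scales the 2012 counts by +4.3% for 2016 conditions.
#'
#' @param residential_raster A [raster_field()] of persons per cell.
#' @param growth_factor Multiplicative growth factor (> 0), e.g. `1.043`.
#' @return A `population_inventory` with the grown raster and its total.
#' @export
population_inventory <- function(residential_raster, growth_factor = 1) {
  grown <- apply_growth(residential_raster, growth_factor)
  structure(
    list(residential_raster = grown, total_population = sum(grown$values),
         growth_factor = growth_factor),
    class = "population_inventory"
  )
}

#' Scale a population raster by a growth factor
#'
#' @param residential_raster A [raster_field()].
#' @param factor Positive multiplicative factor.
#' @return The cell-wise scaled [raster_field()].
#' @export
apply_growth <- function(residential_raster, factor) {
  if (!is.numeric(factor) || factor <= 0) {
    stop("`factor` must be > 0", call. = FALSE)
  }
  raster_field(residential_raster$grid, residential_raster$values * factor,
               units = residential_raster$units, name = residential_raster$name)
}

day_type_of <- function(times, holidays = NULL) {
  wd <- as.integer(format(times, "%u", tz = "UTC")) # 1 = Monday
  out <- ifelse(wd >= 6, "weekend", "weekday")
  if (!is.null(holidays)) {
    out[as.Date(times, tz = "UTC") %in% as.Date(holidays)] <- "weekend"
  }
  out
}

in_windows <- function(hour, windows) {
  res <- rep(FALSE, length(hour))
  for (w in windows) res <- res | (hour >= w[1] & hour < w[2])
  res
}

# nt x 4 matrix of base-environment totals plus the commuter head count active
# at each hour (attribute "commuters_active").
environment_totals_matrix <- function(inventory, profile, commuters, times,
                                      holidays = NULL) {
  validate_activity_profile(profile)
  dt <- day_type_of(times, holidays)
  hour <- as.integer(format(times, "%H", tz = "UTC"))
  wide <- profile |>
    tidyr::pivot_wider(names_from = "environment", values_from = "fraction")
  key <- paste(wide$day_type, wide$hour)
  idx <- match(paste(dt, hour), key)
  if (anyNA(idx)) stop("activity profile does not cover all hours/day types", call. = FALSE)
  frac <- as.matrix(wide[idx, base_environments()])
  totals <- inventory$total_population * frac
  active <- numeric(length(times))
  if (!is.null(commuters) && commuters$count > 0) {
    workday <- if (commuters$workday_only) dt == "weekday" else rep(TRUE, length(times))
    rush <- workday & in_windows(hour, commuters$rush_windows)
    working <- workday & !rush & hour >= commuters$work_hours[1] & hour < commuters$work_hours[2]
    totals[rush, "transport"] <- totals[rush, "transport"] + commuters$count
    totals[working, "work"] <- totals[working, "work"] + commuters$count
    active[rush | working] <- commuters$count
  }
  attr(totals, "commuters_active") <- active
  totals
}

#' Hourly population totals per base environment
#'
#' For one timestamp, the total population in each base environment: the
#' activity-profile fraction for that hour and day type times the total
#' population, plus commuters placed in transport during rush windows and in
#' work during working hours on workdays.
#'
#' @param inventory A [population_inventory()].
#' @param profile Activity-profile tibble, see [default_activity_profiles()].
#' @param commuters A [commuter_spec()] or `NULL`.
#' @param timestamp A `POSIXct` instant (UTC).
#' @param holidays Optional vector of dates treated as weekends.
#' @return A tibble with columns `environment` and `persons`.
#' @export
hourly_environment_totals <- function(inventory, profile, commuters = NULL,
                                      timestamp, holidays = NULL) {
  m <- environment_totals_matrix(inventory, profile, commuters,
                                 as.POSIXct(timestamp, tz = "UTC"), holidays)
  tibble::tibble(environment = base_environments(), persons = as.numeric(m[1, ]))
}

#' Split a transport-environment total over the seven modes
#'
#' @param transport_total Persons in the transport environment (>= 0).
#' @param split Modal-split tibble (`mode`, `fraction`) summing to 1, see
#'   [hamburg_modal_split()].
#' @return A tibble with columns `mode` and `persons`; mode totals sum to the
#'   input total.
#' @export
split_transport_total <- function(transport_total, split = hamburg_modal_split()) {
  stopifnot(transport_total >= 0)
  validate_modal_split(split)
  tibble::tibble(mode = split$mode, persons = transport_total * split$fraction)
}

#' Distribute a population total uniformly over a mask
#'
#' Every `TRUE` cell receives `total / n_true`; all other cells 0. This equal
#' distribution over the environment's cells is the spatial allocation rule
#' for the work, other and transport(-mode) environments.
#'
#' @param total Persons (>= 0).
#' @param mask Logical [raster_field()].
#' @param name Environment name, used in error messages.
#' @return A [raster_field()] in persons summing to `total`.
#' @export
distribute_to_mask <- function(total, mask, name = mask$name) {
  stopifnot(total >= 0)
  n_true <- sum(mask$values)
  if (total > 0 && n_true == 0) {
    stop(sprintf("cannot distribute %g persons: environment '%s' has an empty mask",
                 total, name), call. = FALSE)
  }
  vals <- matrix(0, nrow = mask$grid$n_y, ncol = mask$grid$n_x)
  if (n_true > 0) vals[mask$values] <- total / n_true
  raster_field(mask$grid, vals, units = "persons", name = name)
}

#' Build hourly population stacks for an exposure approach
#'
#' Produces one [hourly_stack()] of persons per cell for every environment the
#' approach uses:
#' * `static` — the whole population sits in `home` at all hours, frozen at
#'   the (growth-scaled) residential raster;
#' * `dynamic` — `home`, `work`, `other` and one undivided `transport`
#'   environment follow the activity profile;
#' * `dynamic_transport` — as `dynamic` for `home`/`work`/`other` (identical
#'   stacks by construction), with the transport total split over the seven
#'   mode environments by the modal split.
#'
#' The hourly `home` total is spread over cells proportionally to the
#' residential raster; all other environments are spread uniformly over their
#' mask cells. For every hour the grand total over environments equals the
#' total population plus the commuters scheduled in that hour.
#'
#' @inheritParams hourly_environment_totals
#' @param split Modal-split tibble; required for `dynamic_transport`.
#' @param masks An `env_mask_set` covering every environment the approach
#'   needs (base masks for `dynamic`, mode masks for `dynamic_transport`).
#' @param approach One of `"static"`, `"dynamic"`, `"dynamic_transport"`.
#' @param times Hourly `POSIXct` axis.
#' @return Named list of [hourly_stack()]s, one per environment.
#' @export
build_hourly_population <- function(inventory, profile = default_activity_profiles(),
                                    commuters = NULL, split = hamburg_modal_split(),
                                    masks = NULL,
                                    approach = c("dynamic_transport", "dynamic", "static"),
                                    times, holidays = NULL) {
  approach <- match.arg(approach)
  grid <- inventory$residential_raster$grid
  res <- inventory$residential_raster$values
  total <- inventory$total_population
  home_pattern <- if (total > 0) res / total else res * 0

  stack_from_pattern <- function(tot_vec, pattern) {
    hourly_stack(grid, times, outer(tot_vec, pattern), units = "persons")
  }
  uniform_pattern <- function(env) {
    if (is.null(masks) || is.null(masks[[env]])) {
      stop(sprintf("approach '%s' requires a mask for environment '%s'",
                   approach, env), call. = FALSE)
    }
    d <- distribute_to_mask(1, masks[[env]], name = env)
    d$values
  }

  if (approach == "static") {
    return(list(home = stack_from_pattern(rep(total, length(times)), home_pattern)))
  }

  totals <- environment_totals_matrix(inventory, profile, commuters, times, holidays)
  out <- list(
    home = stack_from_pattern(totals[, "home"], home_pattern),
    work = stack_from_pattern(totals[, "work"], uniform_pattern("work")),
    other = stack_from_pattern(totals[, "other"], uniform_pattern("other"))
  )
  if (approach == "dynamic") {
    out$transport <- stack_from_pattern(totals[, "transport"], uniform_pattern("transport"))
  } else {
    validate_modal_split(split)
    for (mode in transport_modes()) {
      frac <- split$fraction[split$mode == mode]
      if (length(frac) != 1) stop(sprintf("modal split misses mode '%s'", mode), call. = FALSE)
      out[[mode]] <- stack_from_pattern(totals[, "transport"] * frac,
                                        uniform_pattern(mode))
    }
  }
  out
}
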