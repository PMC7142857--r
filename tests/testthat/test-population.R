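test_that("growth scaling is exact and cell-wise", {
  g <- tiny_grid(2, 2, 100)
  r <- raster_field(g, matrix(c(4e5, 3e5, 2e5, 1e5), 2, 2), units = "persons")
  expect_equal(sum(apply_growth(r, 1.043)$values), 1043000)
  expect_identical(apply_growth(r, 1)$values, r$values)
  expect_identical(apply_growth(r, 2)$values, r$values * 2)
  expect_error(apply_growth(r, 0), "> 0")
})

test_that("hourly environment totals follow profile fractions and commuters", {
  g <- tiny_grid(2, 2, 100)
  inv <- population_inventory(raster_field(g, matrix(250, 2, 2), units = "persons"))
  all_home <- tidyr::crossing(day_type = c("weekday", "weekend"), hour = 0:23,
                              environment = base_environments()) |>
    dplyr::mutate(fraction = ifelse(environment == "home", 1, 0))
  t0 <- as.POSIXct("2016-01-06 03:00", tz = "UTC") # a Wednesday
  tot <- hourly_environment_totals(inv, all_home, NULL, t0)
  expect_equal(tot$persons[tot$environment == "home"], 1000)
  expect_equal(sum(tot$persons), 1000)

  prof <- tidyr::crossing(day_type = c("weekday", "weekend"), hour = 0:23) |>
    tidyr::crossing(tibble::tibble(environment = base_environments(),
                                   fraction = c(0.5, 0.3, 0.1, 0.1)))
  tot2 <- hourly_environment_totals(inv, prof, NULL, t0)
  expect_equal(tot2$persons, c(500, 300, 100, 100))

  # weekday 08:00 falls in a rush window: commuters land in transport
  t_rush <- as.POSIXct("2016-01-06 08:00", tz = "UTC")
  tot3 <- hourly_environment_totals(inv, prof, commuter_spec(223000), t_rush)
  expect_equal(tot3$persons[tot3$environment == "transport"], 100 + 223000)
  # midday they sit in work; weekends they are absent
  t_work <- as.POSIXct("2016-01-06 12:00", tz = "UTC")
  tot4 <- hourly_environment_totals(inv, prof, commuter_spec(223000), t_work)
  expect_equal(tot4$persons[tot4$environment == "work"], 300 + 223000)
  t_sat <- as.POSIXct("2016-01-09 08:00", tz = "UTC")
  tot5 <- hourly_environment_totals(inv, prof, commuter_spec(223000), t_sat)
  expect_equal(sum(tot5$persons), 1000)
})

test_that("profiles that do not sum to 1 fail validation at load time", {
  bad <- default_activity_profiles()
  bad$fraction[1] <- bad$fraction[1] + 0.01
  expect_error(validate_activity_profile(bad), "not summing to 1")
})

test_that("the default modal split reproduces the printed shares, ferry dropped", {
  ms <- hamburg_modal_split()
  expect_equal(sum(ms$fraction), 1, tolerance = 1e-12)
  expect_equal(ms$fraction[ms$mode == "walking"], 0.27)
  expect_equal(ms$fraction[ms$mode == "cycling"], 0.15)
  expect_equal(ms$fraction[ms$mode == "in_car"], 0.36)
  # public-transport sub-split renormalized after the 1% ferry exclusion
  expect_equal(ms$fraction[ms$mode == "buses"], 0.22 * 0.36 / 0.99)
  expect_equal(ms$fraction[ms$mode == "subway_trains"], 0.22 * 0.32 / 0.99)
})

test_that("transport totals split over modes and sum back exactly", {
  st <- split_transport_total(1000)
  expect_equal(st$persons[st$mode == "in_car"], 360)
  expect_equal(sum(st$persons), 1000)

  only_walk <- tibble::tibble(mode = transport_modes(),
                              fraction = c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(split_transport_total(50, only_walk)$persons[1], 50)

  # two-level product oracle over 10,000 persons
  st2 <- split_transport_total(10000)
  expect_equal(st2$persons[st2$mode == "walking"], 10000 * 0.27)
  expect_equal(st2$persons[st2$mode == "suburban_trains"],
               10000 * 0.22 * 0.25 / 0.99)
  bad <- tibble::tibble(mode = transport_modes(), fraction = rep(0.2, 7))
  expect_error(split_transport_total(10, bad), "sum to")
})

test_that("uniform mask distribution conserves totals and flags empty masks", {
  g <- tiny_grid(2, 2, 100)
  m4 <- raster_field(g, matrix(TRUE, 2, 2), units = "bool", name = "work")
  d <- distribute_to_mask(100, m4)
  expect_true(all(d$values == 25))
  expect_equal(sum(distribute_to_mask(0, m4)$values), 0)

  m3 <- raster_field(g, matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2), units = "bool",
                     name = "other")
  d3 <- distribute_to_mask(17, m3)
  expect_equal(sum(d3$values), 17)
  expect_equal(max(d3$values), 17 / 3)

  empty <- raster_field(g, matrix(FALSE, 2, 2), units = "bool", name = "subway_trains")
  expect_error(distribute_to_mask(5, empty), "subway_trains")
})

test_that("hourly population builds conserve people and share base environments", {
  city <- small_city(seed = 2)
  inv <- city_inventory(city)
  masks <- build_city_masks(city)
  times <- hourly_times("2016-01-04", 24)
  commuters <- commuter_spec(5000)

  static <- build_hourly_population(inv, commuters = commuters, masks = masks,
                                    approach = "static", times = times)
  expect_equal(names(static), "home")
  for (t in c(1, 12, 24)) {
    expect_identical(static$home$values[t, , ], static$home$values[1, , ])
  }
  expect_equal(sum(static$home$values[1, , ]), inv$total_population)

  dyn <- build_hourly_population(inv, commuters = commuters, masks = masks,
                                 approach = "dynamic", times = times)
  dynt <- build_hourly_population(inv, commuters = commuters, masks = masks,
                                  approach = "dynamic_transport", times = times)
  for (env in c("home", "work", "other")) {
    expect_identical(dyn[[env]]$values, dynt[[env]]$values)
  }

  # per-hour accounting: totals equal population + scheduled commuters, and
  # mode totals rebuild the undivided transport total
  hour <- as.integer(format(times, "%H", tz = "UTC"))
  rush <- hour %in% c(7, 8, 16, 17, 18)
  working <- !rush & hour >= 9 & hour < 16
  scheduled <- ifelse(rush | working, 5000, 0) # weekday
  for (t in seq_along(times)) {
    tot_dyn <- sum(vapply(dyn, function(s) sum(s$values[t, , ]), numeric(1)))
    tot_dynt <- sum(vapply(dynt, function(s) sum(s$values[t, , ]), numeric(1)))
    expect_equal(tot_dyn, inv$total_population + scheduled[t], tolerance = 1e-9)
    expect_equal(tot_dynt, inv$total_population + scheduled[t], tolerance = 1e-9)
    mode_sum <- sum(vapply(transport_modes(),
                           function(m) sum(dynt[[m]]$values[t, , ]), numeric(1)))
    expect_equal(mode_sum, sum(dyn$transport$values[t, , ]), tolerance = 1e-9)
  }
})

test_that("a 100%-home profile makes the dynamic build degenerate to static", {
  city <- small_city(seed = 4)
  inv <- city_inventory(city)
  masks <- build_city_masks(city)
  times <- hourly_times("2016-02-01", 12)
  all_home <- tidyr::crossing(day_type = c("weekday", "weekend"), hour = 0:23,
                              environment = base_environments()) |>
    dplyr::mutate(fraction = ifelse(environment == "home", 1, 0))
  dyn <- build_hourly_population(inv, profile = all_home, masks = masks,
                                 approach = "dynamic", times = times)
  static <- build_hourly_population(inv, masks = masks, approach = "static",
                                    times = times)
  expect_equal(dyn$home$values, static$home$values, tolerance = 1e-12)
  expect_true(all(dyn$work$values == 0))
})
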