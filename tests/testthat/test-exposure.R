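finf_one <- function(envs, pollutant = "X") {
  tidyr::crossing(environment = envs, pollutant = pollutant,
                  season = c("winter", "summer")) |>
    dplyr::mutate(finf = 1)
}

test_that("point exposure is the C x P x F product", {
  expect_equal(cell_exposure(10, 5, 1), 50)
  expect_equal(cell_exposure(10, 5, 0.5), 25)
  expect_equal(cell_exposure(0, 123, 0.7), 0)
  expect_error(cell_exposure(10, -1, 1), ">= 0")
  expect_error(cell_exposure(Inf, 1, 1), "finite")
})

test_that("total exposure reproduces a hand-summed single-cell case", {
  g <- tiny_grid(1, 1, 100)
  times <- hourly_times("2016-06-01", 2)
  conc <- hourly_stack(g, times, array(c(10, 20), c(2, 1, 1)), units = "ug/m3")
  pop <- list(e1 = hourly_stack(g, times, array(1, c(2, 1, 1)), units = "persons"))
  res <- total_exposure(conc, pop, finf_one("e1"), "X")
  expect_equal(res$envs$e1[1, 1], 30)
  expect_equal(res$totals$exposure, 30)

  pop0 <- list(e1 = hourly_stack(g, times, array(0, c(2, 1, 1)), units = "persons"))
  expect_equal(total_exposure(conc, pop0, finf_one("e1"), "X")$totals$exposure, 0)
})

test_that("total exposure and PWE match brute-force loop oracles", {
  set.seed(99)
  g <- tiny_grid(3, 3, 100)
  times <- hourly_times("2016-03-31", 24) # spans both seasons
  conc <- rand_stack(g, times)
  envs <- c("home", "work", transport_modes()[1:2])
  pop <- rand_population(g, times, envs)
  finf <- rand_finf_table(envs)
  res <- total_exposure(conc, pop, finf, "X")
  oracle <- oracle_total_exposure(conc, pop, finf, "X")
  for (env in envs) {
    expect_equal(res$envs[[env]], oracle[[env]], tolerance = 1e-9)
  }
  pwe <- population_weighted_exposure(conc, pop, finf, "X")
  expect_equal(pwe$pwe, oracle_pwe(conc, pop, finf, "X"), tolerance = 1e-9)
})

test_that("exposure is linear in concentration, population and infiltration", {
  set.seed(5)
  g <- tiny_grid(2, 2, 100)
  times <- hourly_times("2016-05-01", 12)
  c1 <- rand_stack(g, times); c2 <- rand_stack(g, times)
  pop1 <- rand_population(g, times, c("home", "work"))
  finf <- rand_finf_table(c("home", "work"))
  e1 <- total_exposure(c1, pop1, finf, "X")$totals$exposure
  e2 <- total_exposure(c2, pop1, finf, "X")$totals$exposure
  csum <- hourly_stack(g, times, c1$values + 2 * c2$values, units = "ug/m3")
  esum <- total_exposure(csum, pop1, finf, "X")$totals$exposure
  expect_equal(esum, e1 + 2 * e2, tolerance = 1e-12)

  pop2 <- lapply(pop1, function(s) hourly_stack(g, times, 3 * s$values, units = "persons"))
  expect_equal(total_exposure(c1, pop2, finf, "X")$totals$exposure, 3 * e1,
               tolerance = 1e-12)
  expect_equal(total_exposure(c1, pop1, scale_finf(finf, 0.5), "X")$totals$exposure,
               0.5 * e1, tolerance = 1e-12)
})

test_that("PWE equals the concentration under uniform fields and respects bounds", {
  g <- tiny_grid(2, 2, 100)
  times <- hourly_times("2016-06-01", 6)
  conc <- hourly_stack(g, times, 8, units = "ug/m3")
  pop <- rand_population(g, times, "home", p_zero = 0)
  expect_equal(population_weighted_exposure(conc, pop, finf_one("home"), "X")$pwe, 8)
  half <- finf_one("home") |> dplyr::mutate(finf = 0.5)
  expect_equal(population_weighted_exposure(conc, pop, half, "X")$pwe, 4)

  # two cells, person-hours 3:1 at c = (10, 30) -> weighted mean 15
  g2 <- make_grid(0, 0, 2, 1, 100, "t")
  t1 <- hourly_times("2016-06-01", 1)
  conc2 <- hourly_stack(g2, t1, array(c(10, 30), c(1, 1, 2)), units = "ug/m3")
  pop2 <- list(home = hourly_stack(g2, t1, array(c(3, 1), c(1, 1, 2)), units = "persons"))
  expect_equal(population_weighted_exposure(conc2, pop2, finf_one("home"), "X")$pwe, 15)

  # bounds: min(F C) <= PWE <= max(F C) over visited cell-hours
  set.seed(31)
  conc3 <- rand_stack(g, times)
  pop3 <- rand_population(g, times, c("home", "work"))
  finf3 <- rand_finf_table(c("home", "work"))
  pw <- population_weighted_exposure(conc3, pop3, finf3, "X")
  fc <- unlist(lapply(c("home", "work"), function(env) {
    f <- resolve_finf(finf3, env, "X", times)
    visited <- pop3[[env]]$values > 0
    (array(f, dim(conc3$values)) * conc3$values)[visited]
  }))
  expect_gte(pw$pwe, min(fc))
  expect_lte(pw$pwe, max(fc))
})

test_that("PWE of an empty scope is missing, not zero", {
  g <- tiny_grid(2, 2, 100)
  times <- hourly_times("2016-06-01", 3)
  conc <- hourly_stack(g, times, 5, units = "ug/m3")
  pop <- list(work = hourly_stack(g, times, 0, units = "persons"))
  expect_warning(pw <- population_weighted_exposure(conc, pop, finf_one("work"), "X"),
                 "zero cumulative population")
  expect_true(is.na(pw$pwe))
})

test_that("zero-out contributions recover constructed ground truth additively", {
  set.seed(17)
  g <- tiny_grid(3, 3, 100)
  times <- hourly_times("2016-09-30", 12)
  zero <- rand_stack(g, times, lo = 5, hi = 15)
  increment <- rand_stack(g, times, lo = 0, hi = 10)
  full <- hourly_stack(g, times, zero$values + increment$values, units = "ug/m3")
  pop <- rand_population(g, times, c("home", "walking"))
  finf <- rand_finf_table(c("home", "walking"))

  contrib <- source_contribution(full, zero, pop, finf, "X")
  e_inc <- total_exposure(increment, pop, finf, "X")
  expect_equal(contrib$by_environment$contribution, e_inc$totals$exposure,
               tolerance = 1e-9)
  expect_true(all(contrib$by_environment$relative >= 0 &
                    contrib$by_environment$relative <= 1))

  # additivity: contribution + zero-out exposure = full exposure, per environment
  e_zero <- total_exposure(zero, pop, finf, "X")
  e_full <- total_exposure(full, pop, finf, "X")
  expect_equal(contrib$by_environment$contribution + e_zero$totals$exposure,
               e_full$totals$exposure, tolerance = 1e-9)

  # degenerate cases
  same <- source_contribution(full, full, pop, finf, "X")
  expect_true(all(same$by_environment$contribution == 0))
  nothing <- hourly_stack(g, times, 0, units = "ug/m3")
  all_src <- source_contribution(full, nothing, pop, finf, "X")
  pos <- all_src$by_environment$exposure_full > 0
  expect_equal(all_src$by_environment$relative[pos], rep(1, sum(pos)))
})

test_that("negative differences are kept and flagged, never clipped", {
  g <- tiny_grid(2, 2, 100)
  times <- hourly_times("2016-06-01", 2)
  full <- hourly_stack(g, times, 1, units = "ug/m3")
  zero <- hourly_stack(g, times, 2, units = "ug/m3")
  pop <- list(home = hourly_stack(g, times, 1, units = "persons"))
  expect_warning(res <- source_contribution(full, zero, pop, finf_one("home"), "X"),
                 "zero-out exceeds")
  expect_lt(res$by_environment$contribution, 0)
})

test_that("environment shares are normalized fractions of the scope total", {
  g <- tiny_grid(1, 1, 100)
  times <- hourly_times("2016-06-01", 1)
  conc <- hourly_stack(g, times, 1, units = "ug/m3")
  mk_pop <- function(v) hourly_stack(g, times, array(v, c(1, 1, 1)), units = "persons")
  pop <- list(home = mk_pop(3), work = mk_pop(1))
  res <- total_exposure(conc, pop, finf_one(c("home", "work")), "X")
  sh <- environment_shares(res)
  expect_equal(sh$share, c(0.75, 0.25))

  only <- total_exposure(conc, pop["home"], finf_one("home"), "X")
  expect_equal(environment_shares(only)$share, 1)

  pop7 <- stats::setNames(lapply(1:7, function(i) mk_pop(i)), transport_modes())
  res7 <- total_exposure(conc, pop7, finf_one(transport_modes()), "X")
  expect_equal(sum(environment_shares(res7, "transport_modes")$share), 1,
               tolerance = 1e-9)

  zero_pop <- list(home = mk_pop(0))
  res0 <- total_exposure(conc, zero_pop, finf_one("home"), "X")
  expect_warning(sh0 <- environment_shares(res0), "zero scope total")
  expect_true(is.na(sh0$share))
})

test_that("tidy and glance summarize exposure results", {
  g <- tiny_grid(2, 2, 100)
  times <- hourly_times("2016-06-01", 3)
  conc <- hourly_stack(g, times, 5, units = "ug/m3")
  pop <- rand_population(g, times, c("home", "work"), p_zero = 0)
  res <- total_exposure(conc, pop, finf_one(c("home", "work")), "X",
                        approach = "dynamic")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(res)
  expect_equal(gl$total_exposure, sum(td$exposure))
  expect_equal(gl$n_hours, 3)
})
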