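# Shared fixtures and independent oracles. Oracles deliberately use plain
# loops and direct table subsetting so they share no code path with the
# implementation they check.

tiny_grid <- function(nx = 3, ny = 3, cs = 100) make_grid(0, 0, nx, ny, cs, "test")

rand_stack <- function(grid, times, lo = 0, hi = 30, start = "2016-03-30") {
  if (!inherits(times, "POSIXct")) times <- hourly_times(start, times)
  nt <- length(times)
  hourly_stack(grid, times,
               array(stats::runif(nt * grid$n_y * grid$n_x, lo, hi),
                     dim = c(nt, grid$n_y, grid$n_x)),
               units = "ug/m3")
}

rand_finf_table <- function(envs, pollutant = "X") {
  tidyr::crossing(environment = envs, pollutant = pollutant,
                  season = c("winter", "summer")) |>
    dplyr::mutate(finf = stats::runif(dplyr::n(), 0.3, 1))
}

# direct month-based seasonal lookup, independent of season_of()/resolve_finf()
oracle_finf <- function(table, env, pollutant, time1) {
  mo <- as.POSIXlt(time1, tz = "UTC")$mon + 1
  season <- if (mo %in% c(10, 11, 12, 1, 2, 3)) "winter" else "summer"
  table$finf[table$environment == env & table$pollutant == pollutant &
               table$season == season]
}

# brute-force triple loop over environments, cells and hours
oracle_total_exposure <- function(conc, pop, finf_table, pollutant) {
  out <- list()
  for (env in names(pop)) {
    E <- matrix(0, conc$grid$n_y, conc$grid$n_x)
    for (iy in seq_len(conc$grid$n_y)) {
      for (ix in seq_len(conc$grid$n_x)) {
        s <- 0
        for (t in seq_along(conc$times)) {
          f <- oracle_finf(finf_table, env, pollutant, conc$times[t])
          s <- s + f * conc$values[t, iy, ix] * pop[[env]]$values[t, iy, ix]
        }
        E[iy, ix] <- s
      }
    }
    out[[env]] <- E
  }
  out
}

oracle_pwe <- function(conc, pop, finf_table, pollutant) {
  E <- oracle_total_exposure(conc, pop, finf_table, pollutant)
  num <- 0; den <- 0
  for (env in names(pop)) {
    num <- num + sum(E[[env]])
    for (t in seq_along(conc$times)) den <- den + sum(pop[[env]]$values[t, , ])
  }
  if (den > 0) num / den else NA_real_
}

# dense point sampling of a segment mapped to cells (half-open indexing)
supersample_cells <- function(x0, y0, x1, y1, grid, step = 1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  tt <- if (len == 0) 0 else seq(0, 1, by = step / len)
  tt <- unique(c(tt, 1))
  px <- x0 + tt * (x1 - x0)
  py <- y0 + tt * (y1 - y0)
  idx <- cell_index(grid, px, py)
  ok <- !is.na(idx$col)
  unique(paste(idx$col[ok], idx$row[ok]))
}

mask_cells <- function(mask) {
  w <- which(mask$values, arr.ind = TRUE)
  if (nrow(w) == 0) return(character(0))
  sort(paste(w[, 2] - 1L, w[, 1] - 1L)) # "col row", 0-based
}

# small random per-environment population stacks on a grid/time axis
rand_population <- function(grid, times, envs, p_zero = 0.2) {
  nt <- length(times)
  out <- lapply(envs, function(e) {
    v <- array(stats::runif(nt * grid$n_y * grid$n_x, 0, 50),
               dim = c(nt, grid$n_y, grid$n_x))
    v[stats::runif(length(v)) < p_zero] <- 0
    hourly_stack(grid, times, v, units = "persons")
  })
  names(out) <- envs
  out
}

small_city <- function(seed = 1, ...) {
  generate_city(synthetic_city_spec(seed = seed, ...))
}

city_inventory <- function(city, growth = 1.043) {
  population_inventory(
    rasterize_population_polygons(
      city$lulc[city$lulc$class == "residential", , drop = FALSE], city$grid),
    growth
  )
}
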