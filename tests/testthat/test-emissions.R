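mk_links <- function(...) dplyr::bind_rows(...)
mk_link <- function(id, type, m) {
  tibble::tibble(link_id = id, road_type = type, geometry = list(m))
}

test_that("urban-core cells are scaled by the configured factor", {
  g <- tiny_grid(2, 2, 1000)
  eg <- emission_grid(g, list(NO2 = matrix(c(9, 1, 2, 3), 2, 2)))
  mask <- raster_field(g, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), units = "bool")
  scaled <- scale_urban_cells(eg, mask, 3)
  expect_equal(scaled$totals$NO2[1, 1], 27)
  expect_equal(scaled$totals$NO2[2, ], eg$totals$NO2[2, ])

  none <- raster_field(g, matrix(FALSE, 2, 2), units = "bool")
  expect_identical(scale_urban_cells(eg, none, 3)$totals$NO2, eg$totals$NO2)
  expect_error(scale_urban_cells(eg, raster_field(tiny_grid(3, 3), FALSE, units = "b"), 3),
               "does not match")
})

test_that("cell disaggregation weights by length times road-type weight", {
  one <- tibble::tibble(link_id = "a", length = 123, road_type = "primary")
  expect_equal(disaggregate_cell(10, one)$emission, 10)

  two_eq <- tibble::tibble(link_id = c("a", "b"), length = c(200, 200),
                           road_type = "secondary")
  expect_equal(disaggregate_cell(10, two_eq)$emission, c(5, 5))

  lengths <- tibble::tibble(link_id = c("a", "b"), length = c(100, 300),
                            road_type = "primary")
  expect_equal(disaggregate_cell(8, lengths)$emission, c(2, 6))

  types <- tibble::tibble(link_id = c("a", "b"), length = c(150, 150),
                          road_type = c("motorway", "secondary"))
  expect_equal(disaggregate_cell(10, types)$emission, c(8, 2)) # weights 4:1

  expect_error(disaggregate_cell(5, one[0, ]), "no intersecting segments")
  odd <- tibble::tibble(link_id = "x", length = 10, road_type = "alley")
  expect_error(disaggregate_cell(5, odd), "alley")
})

test_that("grid disaggregation conserves mass per cell and globally", {
  g <- tiny_grid(2, 1, 1000)
  eg <- emission_grid(g, list(NO2 = matrix(c(4, 6), 1, 2)))
  link <- mk_link("span", "primary", cbind(c(100, 1900), c(500, 500)))
  res <- disaggregate_grid(eg, link)
  expect_equal(res$links$emission, 10) # sole claimant of both cells
  expect_equal(nrow(res$residual), 0)

  zero <- emission_grid(g, list(NO2 = matrix(0, 1, 2)))
  expect_equal(nrow(disaggregate_grid(zero, link)$links), 0)
})

test_that("cells with emissions but no roads land in the residual ledger", {
  g <- tiny_grid(2, 1, 1000)
  eg <- emission_grid(g, list(NO2 = matrix(c(4, 6), 1, 2)))
  link <- mk_link("west", "primary", cbind(c(100, 900), c(500, 500)))
  expect_warning(res <- disaggregate_grid(eg, link), "residual ledger")
  expect_equal(res$links$emission, 4)
  expect_equal(res$residual$emission, 6)
  expect_equal(res$residual$col, 1)
})

test_that("random fixtures conserve mass against a clipping oracle", {
  set.seed(23)
  for (k in 1:10) {
    g <- tiny_grid(5, 5, 1000)
    vals <- matrix(stats::rpois(25, 4), 5, 5)
    eg <- emission_grid(g, list(NO2 = vals + 0, PM2.5 = vals * 0.2))
    links <- dplyr::bind_rows(lapply(1:12, function(i) {
      mk_link(sprintf("l%02d", i),
              sample(names(default_road_type_weights()), 1),
              cbind(stats::runif(2, 0, 5000), stats::runif(2, 0, 5000)))
    }))
    res <- suppressWarnings(disaggregate_grid(eg, links))
    for (p in c("NO2", "PM2.5")) {
      alloc <- res$allocations[res$allocations$pollutant == p, ]
      resid <- res$residual[res$residual$pollutant == p, ]
      expect_equal(sum(alloc$emission) + sum(resid$emission),
                   sum(eg$totals[[p]]), tolerance = 1e-9)
      # per cell: allocations rebuild the cell total
      per_cell <- alloc |>
        dplyr::summarise(emission = sum(emission), .by = c("row", "col"))
      for (i in seq_len(nrow(per_cell))) {
        expect_equal(per_cell$emission[i],
                     eg$totals[[p]][per_cell$row[i] + 1, per_cell$col[i] + 1],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("disaggregation is invariant to link order and collinear splitting", {
  set.seed(29)
  g <- tiny_grid(3, 3, 1000)
  eg <- emission_grid(g, list(NO2 = matrix(stats::runif(9, 1, 10), 3, 3)))
  links <- dplyr::bind_rows(
    mk_link("a", "motorway", cbind(c(200, 2800), c(1500, 1500))),
    mk_link("b", "secondary", cbind(c(1500, 1500), c(100, 2900))),
    mk_link("c", "primary", cbind(c(300, 2600), c(300, 2700)))
  )
  res1 <- suppressWarnings(disaggregate_grid(eg, links))
  res2 <- suppressWarnings(disaggregate_grid(eg, links[c(3, 1, 2), ]))
  tot1 <- res1$links |> dplyr::arrange(link_id)
  tot2 <- res2$links |> dplyr::arrange(link_id)
  expect_equal(tot1$emission, tot2$emission, tolerance = 1e-12)

  # splitting link "a" into two collinear halves leaves the union allocation
  split_links <- dplyr::bind_rows(
    mk_link("a1", "motorway", cbind(c(200, 1500), c(1500, 1500))),
    mk_link("a2", "motorway", cbind(c(1500, 2800), c(1500, 1500))),
    links[2:3, ]
  )
  res3 <- suppressWarnings(disaggregate_grid(eg, split_links))
  a_whole <- sum(res1$links$emission[res1$links$link_id == "a"])
  a_split <- sum(res3$links$emission[res3$links$link_id %in% c("a1", "a2")])
  expect_equal(a_split, a_whole, tolerance = 1e-9)
})

test_that("urban scaling commutes with disaggregation", {
  g <- tiny_grid(2, 2, 1000)
  eg <- emission_grid(g, list(NO2 = matrix(c(2, 4, 6, 8), 2, 2)))
  mask <- raster_field(g, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2), units = "bool")
  links <- dplyr::bind_rows(
    mk_link("a", "primary", cbind(c(100, 1900), c(500, 500))),
    mk_link("b", "secondary", cbind(c(100, 1900), c(1500, 1500)))
  )
  pre <- disaggregate_grid(scale_urban_cells(eg, mask, 3), links)
  post <- disaggregate_grid(eg, links)
  post$allocations <- post$allocations |>
    dplyr::mutate(emission = emission *
                    ifelse(mask$values[cbind(row + 1, col + 1)], 3, 1))
  post_links <- post$allocations |>
    dplyr::summarise(emission = sum(emission), .by = c("link_id", "pollutant")) |>
    dplyr::arrange(link_id)
  expect_equal(pre$links |> dplyr::arrange(link_id) |> dplyr::pull(emission),
               post_links$emission, tolerance = 1e-12)
})

test_that("scenario scaling is per-pollutant and multiplicative", {
  g <- tiny_grid(1, 1, 1000)
  eg <- emission_grid(g, list(NO2 = matrix(1, 1, 1), PM2.5 = matrix(1, 1, 1)))
  link <- mk_link("a", "primary", cbind(c(100, 900), c(500, 500)))
  res <- disaggregate_grid(eg, link)
  ref <- scenario_scale(res, c(NO2 = 1.3, PM2.5 = 1.2))
  expect_equal(ref$links$emission[ref$links$pollutant == "NO2"], 1.3)
  expect_equal(ref$links$emission[ref$links$pollutant == "PM2.5"], 1.2)

  expect_equal(scenario_scale(res, c(NO2 = 1))$links$emission, res$links$emission)
  ab <- scenario_scale(scenario_scale(res, c(NO2 = 1.3)), c(NO2 = 1.4 / 1.3))
  direct <- scenario_scale(res, c(NO2 = 1.4))
  expect_equal(ab$links$emission, direct$links$emission, tolerance = 1e-12)
  expect_error(scenario_scale(res, c(SO2 = 2)), "unknown pollutant")
})
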