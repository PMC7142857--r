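# File I/O: comment-header CSV for rasters and hourly stacks, GeoJSON for
# vector inputs. The CSV dialect is comma-separated with "." decimal and a
# header row; grid geometry travels in '#key=value' comment lines so that a
# round-trip preserves geometry, units and values.

grid_header_lines <- function(grid, units, extra = character()) {
  c(
    sprintf("#x_origin=%.15g", grid$x_origin),
    sprintf("#y_origin=%.15g", grid$y_origin),
    sprintf("#n_x=%d", grid$n_x),
    sprintf("#n_y=%d", grid$n_y),
    sprintf("#cell_size=%.15g", grid$cell_size),
    sprintf("#crs_id=%s", grid$crs_id),
    sprintf("#units=%s", units),
    extra
  )
}

parse_header <- function(lines) {
  kv <- lines[startsWith(lines, "#")]
  kv <- sub("^#", "", kv)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

header_grid <- function(h) {
  make_grid(
    as.numeric(h$x_origin), as.numeric(h$y_origin),
    as.integer(h$n_x), as.integer(h$n_y),
    as.numeric(h$cell_size), h$crs_id
  )
}

#' Read and write raster fields and hourly stacks as CSV
#'
#' `write_raster_csv()` stores a [raster_field()] as a long CSV
#' (`row,col,value`, 0-based indices, row 0 at the south edge) under a
#' comment header carrying the grid geometry and units. `write_stack_csv()`
#' does the same for an [hourly_stack()] with a leading ISO-8601 `time`
#' column. The readers reverse the operation losslessly (values are printed
#' with 17 significant digits, so doubles round-trip bit-for-bit).
#'
#' @param x A `raster_field` or `hourly_stack`.
#' @param path File path.
#' @param expected_grid Optional `domain_grid`; reading a file whose geometry
#'   differs raises an error naming both geometries.
#' @return The written path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @export
write_raster_csv <- function(x, path) {
  stopifnot(inherits(x, "raster_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(grid_header_lines(x$grid, x$units, sprintf("#name=%s", x$name)), con)
  idx <- which(!is.na(x$values) | TRUE, arr.ind = TRUE) # all cells, fixed order
  df <- data.frame(
    row = idx[, 1] - 1L, col = idx[, 2] - 1L,
    value = sprintf("%.17g", as.numeric(x$values[idx]))
  )
  df <- df[order(df$row, df$col), ]
  writeLines("row,col,value", con)
  writeLines(sprintf("%d,%d,%s", df$row, df$col, df$value), con)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path, expected_grid = NULL) {
  lines <- readLines(path)
  h <- parse_header(lines)
  grid <- header_grid(h)
  if (!is.null(expected_grid) && !grids_equal(grid, expected_grid)) {
    stop_grid_mismatch(grid, expected_grid, sprintf("file '%s'", path))
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = body)
  vals <- matrix(NA_real_, nrow = grid$n_y, ncol = grid$n_x)
  vals[cbind(df$row + 1L, df$col + 1L)] <- df$value
  raster_field(grid, vals, units = h$units, name = h$name %||% "layer")
}

#' @rdname write_raster_csv
#' @export
write_stack_csv <- function(x, path) {
  stopifnot(inherits(x, "hourly_stack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(grid_header_lines(x$grid, x$units), con)
  writeLines("time,row,col,value", con)
  nt <- length(x$times)
  times_txt <- format(x$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  rows <- rep(0:(x$grid$n_y - 1L), times = x$grid$n_x)
  cols <- rep(0:(x$grid$n_x - 1L), each = x$grid$n_y)
  for (t in seq_len(nt)) {
    v <- as.numeric(x$values[t, , ])
    writeLines(sprintf("%s,%d,%d,%.17g", times_txt[t], rows, cols, v), con)
  }
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_stack_csv <- function(path, expected_grid = NULL) {
  lines <- readLines(path)
  h <- parse_header(lines)
  grid <- header_grid(h)
  if (!is.null(expected_grid) && !grids_equal(grid, expected_grid)) {
    stop_grid_mismatch(grid, expected_grid, sprintf("file '%s'", path))
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = body)
  times <- sort(unique(as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")))
  if (length(times) > 1) {
    dt <- diff(as.numeric(times))
    if (any(dt != 3600)) {
      gaps <- times[which(dt != 3600)]
      stop(sprintf("stack in '%s' has gaps in the hourly time axis after: %s",
                   path, paste(format(gaps, tz = "UTC"), collapse = ", ")),
           call. = FALSE)
    }
  }
  vals <- array(NA_real_, dim = c(length(times), grid$n_y, grid$n_x))
  t_idx <- match(as.numeric(as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")),
                 as.numeric(times))
  vals[cbind(t_idx, df$row + 1L, df$col + 1L)] <- df$value
  hourly_stack(grid, times, vals, units = h$units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- GeoJSON -----------------------------------------------------------------

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read vector features from GeoJSON
#'
#' Parses a GeoJSON `FeatureCollection` into a tibble with one row per
#' (single-part) geometry: `LineString`/`MultiLineString` features via
#' `read_geojson_lines()`, `Polygon`/`MultiPolygon` outer rings via
#' `read_geojson_polygons()`. All feature properties become columns; the
#' coordinates become a `geometry` list-column of two-column matrices.
#' Coordinates are taken as-is (planar, already projected).
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with a `geometry` list-column.
#' @export
read_geojson_lines <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  rows <- list()
  for (f in feats) {
    geom <- f$geometry
    props <- lapply(f$properties %||% list(), function(v) if (is.null(v)) NA else v)
    parts <- switch(geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      stop(sprintf("unsupported geometry type '%s' for lines", geom$type), call. = FALSE)
    )
    for (part in parts) {
      rows[[length(rows) + 1L]] <- c(props, list(geometry = list(coords_to_matrix(part))))
    }
  }
  if (length(rows) == 0) return(tibble::tibble(geometry = list()))
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' @rdname read_geojson_lines
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  rows <- list()
  for (f in feats) {
    geom <- f$geometry
    props <- lapply(f$properties %||% list(), function(v) if (is.null(v)) NA else v)
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]), # outer ring
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop(sprintf("unsupported geometry type '%s' for polygons", geom$type), call. = FALSE)
    )
    for (part in parts) {
      rows[[length(rows) + 1L]] <- c(props, list(geometry = list(coords_to_matrix(part))))
    }
  }
  if (length(rows) == 0) return(tibble::tibble(geometry = list()))
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Write line features (with properties) to GeoJSON
#'
#' @param lines A tibble with a `geometry` list-column of coordinate matrices;
#'   all other columns are written as feature properties.
#' @param path Output path.
#' @export
write_geojson_lines <- function(lines, path) {
  props_cols <- setdiff(names(lines), "geometry")
  feats <- lapply(seq_len(nrow(lines)), function(k) {
    m <- lines$geometry[[k]]
    list(
      type = "Feature",
      properties = as.list(lines[k, props_cols, drop = FALSE]),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
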