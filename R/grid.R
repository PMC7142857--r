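#' Define a planar receptor grid
#'
#' The receptor grid is a regular, axis-aligned grid of square cells in a
#' projected (metric) coordinate reference system. Cell `(col = 0, row = 0)`
#' sits at the lower-left (south-west) corner; columns increase eastwards and
#' rows northwards. Cell intervals are half-open:
#' `[origin + k * cell_size, origin + (k + 1) * cell_size)`.
#'
#' @param x_origin,y_origin Coordinates of the grid's lower-left corner, in
#'   metres of the projected CRS.
#' @param n_x,n_y Number of cells in the x (east) and y (north) directions.
#' @param cell_size Cell edge length in metres.
#' @param crs_id Free-text identifier of the projected CRS (e.g.
#'   `"EPSG:32632"`). The package performs no reprojection; all coordinates
#'   must already be in this CRS.
#'
#' @return An object of class `domain_grid`.
#' @examples
#' # a 30 km x 30 km urban domain at 100 m receptor resolution
#' g <- make_grid(0, 0, 300, 300, 100, "utm-like")
#' n_cells(g)
#' @export
make_grid <- function(x_origin, y_origin, n_x, n_y, cell_size, crs_id = "unknown") {
  stopifnot(is.numeric(x_origin), is.numeric(y_origin))
  if (!is.numeric(n_x) || !is.numeric(n_y) || n_x < 1 || n_y < 1 ||
      n_x != as.integer(n_x) || n_y != as.integer(n_y)) {
    stop("`n_x` and `n_y` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number of metres", call. = FALSE)
  }
  structure(
    list(
      x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
      n_x = as.integer(n_x), n_y = as.integer(n_y),
      cell_size = as.numeric(cell_size), crs_id = as.character(crs_id)
    ),
    class = "domain_grid"
  )
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf(
    "<domain_grid> %d x %d cells of %g m (%g x %g km), origin (%g, %g), crs '%s'\n",
    x$n_x, x$n_y, x$cell_size,
    x$n_x * x$cell_size / 1000, x$n_y * x$cell_size / 1000,
    x$x_origin, x$y_origin, x$crs_id
  ))
  invisible(x)
}

#' @rdname make_grid
#' @param grid A `domain_grid`.
#' @export
n_cells <- function(grid) grid$n_x * grid$n_y

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$x_origin, b$x_origin)) &&
    isTRUE(all.equal(a$y_origin, b$y_origin)) &&
    a$n_x == b$n_x && a$n_y == b$n_y &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

stop_grid_mismatch <- function(a, b, what = "input") {
  stop(sprintf(
    "%s grid (%dx%d @ %gm from (%g,%g)) does not match expected grid (%dx%d @ %gm from (%g,%g))",
    what, a$n_x, a$n_y, a$cell_size, a$x_origin, a$y_origin,
    b$n_x, b$n_y, b$cell_size, b$x_origin, b$y_origin
  ), call. = FALSE)
}

#' Cell centres and indexing helpers
#'
#' `cell_centres()` returns the x coordinates of column centres and y
#' coordinates of row centres; centre of cell `(col, row)` (0-based) is at
#' `origin + (k + 0.5) * cell_size`. `cell_index()` maps point coordinates to
#' 0-based `(col, row)` indices under the half-open cell convention, returning
#' `NA` for points outside the grid.
#'
#' @param grid A `domain_grid`.
#' @return For `cell_centres()`, a list with numeric vectors `x` and `y`.
#' @export
cell_centres <- function(grid) {
  list(
    x = grid$x_origin + (seq_len(grid$n_x) - 0.5) * grid$cell_size,
    y = grid$y_origin + (seq_len(grid$n_y) - 0.5) * grid$cell_size
  )
}

#' @rdname cell_centres
#' @param x,y Numeric vectors of point coordinates in the grid CRS.
#' @return For `cell_index()`, a tibble with integer columns `col` and `row`.
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$x_origin) / grid$cell_size)
  row <- floor((y - grid$y_origin) / grid$cell_size)
  bad <- col < 0 | col >= grid$n_x | row < 0 | row >= grid$n_y
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(col = as.integer(col), row = as.integer(row))
}

cell_bounds <- function(grid, col, row) {
  # 0-based col/row -> closed cell square bounds
  list(
    xmin = grid$x_origin + col * grid$cell_size,
    xmax = grid$x_origin + (col + 1) * grid$cell_size,
    ymin = grid$y_origin + row * grid$cell_size,
    ymax = grid$y_origin + (row + 1) * grid$cell_size
  )
}

#' Construct a raster field
#'
#' A `raster_field` couples a [make_grid()] geometry with a matrix of cell
#' values. The matrix is stored with `n_y` rows and `n_x` columns; **row 1 is
#' the southernmost row** (row index grows northwards), matching the grid's
#' 0-based row convention offset by one.
#'
#' @param grid A `domain_grid`.
#' @param values Numeric or logical matrix of shape `(n_y, n_x)`. A single
#'   scalar is recycled.
#' @param units Units string (non-empty), e.g. `"persons"` or `"ug/m3"`.
#' @param name Layer name.
#' @return An object of class `raster_field`.
#' @export
raster_field <- function(grid, values = 0, units = "1", name = "layer") {
  stopifnot(inherits(grid, "domain_grid"))
  if (length(values) == 1) {
    values <- matrix(values, nrow = grid$n_y, ncol = grid$n_x)
  }
  if (!is.matrix(values) || nrow(values) != grid$n_y || ncol(values) != grid$n_x) {
    stop(sprintf("`values` must be a %d x %d matrix (n_y x n_x)", grid$n_y, grid$n_x),
         call. = FALSE)
  }
  if (!nzchar(units)) stop("`units` must be non-empty", call. = FALSE)
  structure(
    list(grid = grid, values = values, units = units, name = name),
    class = "raster_field"
  )
}

#' @export
print.raster_field <- function(x, ...) {
  cat(sprintf(
    "<raster_field '%s'> %d x %d cells [%s], range [%g, %g], sum %g\n",
    x$name, x$grid$n_x, x$grid$n_y, x$units,
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE)),
    sum(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' Construct an hourly field stack
#'
#' A 3-D array of fields on a common grid at a strictly hourly time axis,
#' dimension order `(time, row, col)` with row 1 at the south edge. Used for
#' hourly pollutant concentrations and hourly population fields. A full
#' reference year holds as many layers as the calendar dictates (8784 for a
#' leap year such as 2016); the length is always taken from the time axis,
#' never assumed.
#'
#' @param grid A `domain_grid`.
#' @param times `POSIXct` vector, strictly increasing with exactly one hour
#'   spacing.
#' @param values 3-D array `(length(times), n_y, n_x)`; a scalar is recycled.
#' @param units Units string.
#' @return An object of class `hourly_stack`.
#' @export
hourly_stack <- function(grid, times, values = 0, units = "1") {
  stopifnot(inherits(grid, "domain_grid"), inherits(times, "POSIXct"))
  if (length(times) < 1) stop("empty time axis", call. = FALSE)
  if (length(times) > 1) {
    dt <- diff(as.numeric(times))
    if (any(dt != 3600)) {
      gap <- which(dt != 3600)[1]
      stop(sprintf(
        "time axis must be strictly hourly; step %d (%s -> %s) is %g s",
        gap, format(times[gap], tz = "UTC"), format(times[gap + 1], tz = "UTC"), dt[gap]
      ), call. = FALSE)
    }
  }
  if (length(values) == 1) {
    values <- array(values, dim = c(length(times), grid$n_y, grid$n_x))
  }
  if (!is.array(values) || length(dim(values)) != 3 ||
      !all(dim(values) == c(length(times), grid$n_y, grid$n_x))) {
    stop(sprintf("`values` must be a %d x %d x %d array (time, n_y, n_x)",
                 length(times), grid$n_y, grid$n_x), call. = FALSE)
  }
  structure(
    list(grid = grid, times = times, values = values, units = units),
    class = "hourly_stack"
  )
}

#' @export
print.hourly_stack <- function(x, ...) {
  cat(sprintf(
    "<hourly_stack> %d hours x %d x %d cells [%s], %s .. %s\n",
    length(x$times), x$grid$n_x, x$grid$n_y, x$units,
    format(min(x$times), tz = "UTC"), format(max(x$times), tz = "UTC")
  ))
  invisible(x)
}

#' Build an hourly UTC time axis
#'
#' @param start Start instant, anything `as.POSIXct()` accepts (interpreted in
#'   UTC when given as text).
#' @param n_hours Number of hourly steps.
#' @return A `POSIXct` vector of length `n_hours`.
#' @examples
#' hourly_times("2016-01-04", 48)
#' @export
hourly_times <- function(start, n_hours) {
  start <- as.POSIXct(start, tz = "UTC")
  start + 3600 * (seq_len(n_hours) - 1)
}

stacks_aligned <- function(a, b) {
  grids_equal(a$grid, b$grid) && length(a$times) == length(b$times) &&
    all(as.numeric(a$times) == as.numeric(b$times))
}

check_alignment <- function(a, b, what = "stacks") {
  if (!grids_equal(a$grid, b$grid)) stop_grid_mismatch(a$grid, b$grid, what)
  if (length(a$times) != length(b$times) ||
      !all(as.numeric(a$times) == as.numeric(b$times))) {
    stop(sprintf("%s have mismatching time axes", what), call. = FALSE)
  }
  invisible(TRUE)
}
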