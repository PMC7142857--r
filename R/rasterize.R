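# Planar geometry primitives and rasterization.
#
# Geometry here is deliberately minimal: axis-aligned cell squares against
# segments (Liang-Barsky clipping) and simple polygons (Sutherland-Hodgman
# clipping + shoelace areas). Coordinates are planar metric; anything
# geographic must be projected upstream.

# Clip parametric segment p0 + t*(p1-p0), t in [0,1], to the closed rectangle.
# Returns c(t0, t1) or NULL when the intersection is empty.
clip_segment_rect <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  t0 <- 0
  t1 <- 1
  dx <- x1 - x0
  dy <- y1 - y0
  for (edge in 1:4) {
    if (edge == 1) { p <- -dx; q <- x0 - xmin }
    else if (edge == 2) { p <- dx; q <- xmax - x0 }
    else if (edge == 3) { p <- -dy; q <- y0 - ymin }
    else { p <- dy; q <- ymax - y0 }
    if (p == 0) {
      if (q < 0) return(NULL) # parallel and outside this slab
    } else {
      r <- q / p
      if (p < 0) {
        if (r > t1) return(NULL)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(NULL)
        if (r < t1) t1 <- r
      }
    }
  }
  c(t0, t1)
}

segment_intersects_rect <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  !is.null(clip_segment_rect(x0, y0, x1, y1, xmin, xmax, ymin, ymax))
}

# Length of the part of a segment inside the closed rectangle.
segment_length_in_rect <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  tt <- clip_segment_rect(x0, y0, x1, y1, xmin, xmax, ymin, ymax)
  if (is.null(tt)) return(0)
  (tt[2] - tt[1]) * sqrt((x1 - x0)^2 + (y1 - y0)^2)
}

# Candidate 0-based column/row index ranges for a bounding box, clamped to the
# grid; NULL when the box misses the grid entirely.
candidate_cells <- function(grid, xmin, xmax, ymin, ymax) {
  c0 <- floor((xmin - grid$x_origin) / grid$cell_size)
  c1 <- floor((xmax - grid$x_origin) / grid$cell_size)
  r0 <- floor((ymin - grid$y_origin) / grid$cell_size)
  r1 <- floor((ymax - grid$y_origin) / grid$cell_size)
  if (c1 < 0 || r1 < 0 || c0 >= grid$n_x || r0 >= grid$n_y) return(NULL)
  list(
    cols = max(c0, 0):min(c1, grid$n_x - 1L),
    rows = max(r0, 0):min(r1, grid$n_y - 1L)
  )
}

as_geometry_list <- function(lines) {
  # accept a single coordinate matrix, a list of matrices, or a tibble with a
  # `geometry` list-column
  if (is.matrix(lines)) return(list(lines))
  if (is.data.frame(lines)) {
    if (!"geometry" %in% names(lines)) {
      stop("data-frame input must carry a `geometry` list-column", call. = FALSE)
    }
    return(lines$geometry)
  }
  if (is.list(lines)) return(lines)
  stop("unsupported geometry input", call. = FALSE)
}

#' Rasterize polylines to a boolean membership mask
#'
#' A cell is marked `TRUE` iff at least one polyline touches the cell's closed
#' square (any geometric intersection counts, including a boundary touch).
#' This is the membership rule used to indicate the spatial coverage of a
#' transport mode on the receptor grid.
#'
#' @param lines Polylines: a two-column coordinate matrix, a list of such
#'   matrices, or a tibble with a `geometry` list-column. Coordinates must be
#'   finite and in the grid CRS.
#' @param grid A [make_grid()] grid.
#' @param name Layer name for the resulting mask.
#' @return A logical [raster_field()]. An empty input yields an all-`FALSE`
#'   mask. Geometry extending beyond the grid is clipped with a warning.
#' @export
rasterize_polylines <- function(lines, grid, name = "mask") {
  geoms <- as_geometry_list(lines)
  mask <- matrix(FALSE, nrow = grid$n_y, ncol = grid$n_x)
  clipped <- FALSE
  gx1 <- grid$x_origin + grid$n_x * grid$cell_size
  gy1 <- grid$y_origin + grid$n_y * grid$cell_size
  for (m in geoms) {
    if (is.null(m) || nrow(m) == 0) next
    if (!all(is.finite(m))) stop("polyline coordinates must be finite", call. = FALSE)
    if (any(m[, 1] < grid$x_origin | m[, 1] > gx1 |
            m[, 2] < grid$y_origin | m[, 2] > gy1)) {
      clipped <- TRUE
    }
    n <- nrow(m)
    if (n == 1) {
      idx <- cell_index(grid, m[1, 1], m[1, 2])
      if (!is.na(idx$col[1])) mask[idx$row[1] + 1L, idx$col[1] + 1L] <- TRUE
      next
    }
    for (s in seq_len(n - 1)) {
      x0 <- m[s, 1]; y0 <- m[s, 2]; x1 <- m[s + 1, 1]; y1 <- m[s + 1, 2]
      cand <- candidate_cells(grid, min(x0, x1), max(x0, x1), min(y0, y1), max(y0, y1))
      if (is.null(cand)) next
      for (row in cand$rows) {
        for (col in cand$cols) {
          if (mask[row + 1L, col + 1L]) next
          b <- cell_bounds(grid, col, row)
          if (segment_intersects_rect(x0, y0, x1, y1, b$xmin, b$xmax, b$ymin, b$ymax)) {
            mask[row + 1L, col + 1L] <- TRUE
          }
        }
      }
    }
  }
  if (clipped) warning("polyline coordinates outside the grid were clipped", call. = FALSE)
  raster_field(grid, mask, units = "bool", name = name)
}

# --- polygon machinery -------------------------------------------------------

shoelace_area <- function(m) {
  n <- nrow(m)
  if (n < 3) return(0)
  x <- m[, 1]; y <- m[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of a simple polygon against one half-plane
# keep(x, y) >= 0; inter() returns the edge/boundary intersection point.
clip_halfplane <- function(m, inside, intersect_at) {
  n <- nrow(m)
  if (n == 0) return(m)
  out_x <- numeric(0); out_y <- numeric(0)
  for (k in seq_len(n)) {
    cx <- m[k, 1]; cy <- m[k, 2]
    pk <- if (k == 1) n else k - 1
    px <- m[pk, 1]; py <- m[pk, 2]
    cin <- inside(cx, cy); pin <- inside(px, py)
    if (cin) {
      if (!pin) {
        ip <- intersect_at(px, py, cx, cy)
        out_x <- c(out_x, ip[1]); out_y <- c(out_y, ip[2])
      }
      out_x <- c(out_x, cx); out_y <- c(out_y, cy)
    } else if (pin) {
      ip <- intersect_at(px, py, cx, cy)
      out_x <- c(out_x, ip[1]); out_y <- c(out_y, ip[2])
    }
  }
  cbind(out_x, out_y)
}

# Clip a simple polygon (coordinate matrix, ring not necessarily closed) to an
# axis-aligned rectangle. Returns a coordinate matrix (possibly 0 rows).
clip_polygon_rect <- function(m, xmin, xmax, ymin, ymax) {
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m <- clip_halfplane(m, function(x, y) x >= xmin, function(px, py, cx, cy) {
    t <- (xmin - px) / (cx - px); c(xmin, py + t * (cy - py))
  })
  m <- clip_halfplane(m, function(x, y) x <= xmax, function(px, py, cx, cy) {
    t <- (xmax - px) / (cx - px); c(xmax, py + t * (cy - py))
  })
  m <- clip_halfplane(m, function(x, y) y >= ymin, function(px, py, cx, cy) {
    t <- (ymin - py) / (cy - py); c(px + t * (cx - px), ymin)
  })
  m <- clip_halfplane(m, function(x, y) y <= ymax, function(px, py, cx, cy) {
    t <- (ymax - py) / (cy - py); c(px + t * (cx - px), ymax)
  })
  m
}

polygon_area_in_cell <- function(m, grid, col, row) {
  b <- cell_bounds(grid, col, row)
  shoelace_area(clip_polygon_rect(m, b$xmin, b$xmax, b$ymin, b$ymax))
}

#' Rasterize population-carrying polygons to a persons-per-cell raster
#'
#' Each polygon's population count is allocated to grid cells proportionally
#' to the overlap area between the polygon and the cell square (area-weighted
#' allocation). For polygons fully inside the domain the raster total equals
#' the input total; mass falling outside the grid is dropped with a warning.
#'
#' @param polygons A tibble with a numeric `population` column and a
#'   `geometry` list-column of two-column coordinate matrices (simple rings,
#'   closed or open), or a list of such matrices paired with a `population`
#'   vector.
#' @param grid A [make_grid()] grid.
#' @param population Population counts, only needed when `polygons` is a bare
#'   list of matrices.
#' @return A [raster_field()] in persons per cell.
#' @export
rasterize_population_polygons <- function(polygons, grid, population = NULL) {
  if (is.data.frame(polygons)) {
    geoms <- polygons$geometry
    pop <- polygons$population
  } else {
    geoms <- as_geometry_list(polygons)
    pop <- population
  }
  if (is.null(pop) || length(pop) != length(geoms)) {
    stop("each polygon needs one population count", call. = FALSE)
  }
  if (any(pop < 0)) stop("population counts must be >= 0", call. = FALSE)
  out <- matrix(0, nrow = grid$n_y, ncol = grid$n_x)
  lost <- 0
  for (k in seq_along(geoms)) {
    m <- geoms[[k]]
    a_total <- shoelace_area(m)
    if (a_total <= 0) {
      if (pop[k] > 0) lost <- lost + pop[k]
      next
    }
    cand <- candidate_cells(grid, min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
    allocated <- 0
    if (!is.null(cand)) {
      for (row in cand$rows) {
        for (col in cand$cols) {
          a <- polygon_area_in_cell(m, grid, col, row)
          if (a > 0) {
            w <- a / a_total
            out[row + 1L, col + 1L] <- out[row + 1L, col + 1L] + pop[k] * w
            allocated <- allocated + pop[k] * w
          }
        }
      }
    }
    lost <- lost + (pop[k] - allocated)
  }
  if (lost > 1e-6 * max(sum(pop), 1)) {
    warning(sprintf(
      "%.6g persons fell outside the grid and were dropped (conservation violated by design)",
      lost
    ), call. = FALSE)
  }
  raster_field(grid, out, units = "persons", name = "population")
}
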