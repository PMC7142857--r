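# Microenvironment definitions and mask construction.
#
# Three approaches are supported downstream:
#   static            - one environment (home), from residential addresses
#   dynamic           - home / work / other / transport, from land-use classes
#   dynamic_transport - home / work / other + seven transport-mode
#                       environments from tagged network polylines
# The dynamic approach's single transport mask (land-use based: roads and
# associated land) and the seven mode masks (polyline based) come from
# different sources and are never conflated.

#' Microenvironment identifiers
#'
#' The four base environments are `home`, `work`, `other`, `transport`; the
#' seven transport-mode environments are `walking`, `cycling`, `in_car`,
#' `buses`, `subway_trains`, `suburban_trains`, `regional_trains` (each a
#' child of `transport`). Ferries are deliberately not modelled.
#'
#' @return A character vector of environment ids.
#' @export
base_environments <- function() c("home", "work", "other", "transport")

#' @rdname base_environments
#' @export
transport_modes <- function() {
  c("walking", "cycling", "in_car", "buses",
    "subway_trains", "suburban_trains", "regional_trains")
}

#' @rdname base_environments
#' @export
all_environments <- function() c(base_environments(), transport_modes())

check_environment <- function(env, allowed = all_environments()) {
  if (!env %in% allowed) {
    stop(sprintf("unknown environment '%s' (expected one of: %s)",
                 env, paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(env)
}

#' Default land-use class to microenvironment mapping
#'
#' Maps land-use/land-cover class codes to base environments. The shipped
#' default covers the synthetic city's classes plus common urban-atlas-style
#' names; it is configuration, not ground truth — supply your own mapping to
#' match the land-use product in use. The `transport` row corresponds to the
#' "roads and associated land" class.
#'
#' @return A tibble with columns `class` and `environment`.
#' @export
default_lulc_mapping <- function() {
  tibble::tribble(
    ~class,                   ~environment,
    "residential",            "home",
    "urban_fabric",           "home",
    "industrial_commercial",  "work",
    "industrial",             "work",
    "commercial",             "work",
    "green_urban",            "other",
    "sports_leisure",         "other",
    "forest",                 "other",
    "roads_associated_land",  "transport"
  )
}

#' Build base-environment masks from land-use polygons
#'
#' A cell belongs to an environment iff at least one polygon of a class mapped
#' to that environment intersects the cell square with positive area.
#' Polygons whose class is absent from the mapping are ignored with a warning.
#'
#' @param lulc_polygons Tibble with columns `class` and `geometry` (list of
#'   two-column coordinate matrices), e.g. from [read_geojson_polygons()].
#' @param mapping Tibble `class` -> `environment`, see
#'   [default_lulc_mapping()].
#' @param grid A [make_grid()] grid.
#' @return An `env_mask_set`: named list of logical [raster_field()] masks
#'   sharing one grid, with attribute `grid`.
#' @export
build_base_environments <- function(lulc_polygons, mapping = default_lulc_mapping(),
                                    grid) {
  unknown <- setdiff(unique(lulc_polygons$class), mapping$class)
  if (length(unknown) > 0) {
    warning(sprintf("land-use classes not in mapping, ignored: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  masks <- lapply(base_environments(), function(env) {
    classes <- mapping$class[mapping$environment == env]
    sel <- lulc_polygons$class %in% classes
    mask <- matrix(FALSE, nrow = grid$n_y, ncol = grid$n_x)
    for (m in lulc_polygons$geometry[sel]) {
      cand <- candidate_cells(grid, min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
      if (is.null(cand)) next
      for (row in cand$rows) {
        for (col in cand$cols) {
          if (!mask[row + 1L, col + 1L] &&
              polygon_area_in_cell(m, grid, col, row) > 0) {
            mask[row + 1L, col + 1L] <- TRUE
          }
        }
      }
    }
    raster_field(grid, mask, units = "bool", name = env)
  })
  names(masks) <- base_environments()
  structure(masks, grid = grid, class = "env_mask_set")
}

#' @export
print.env_mask_set <- function(x, ...) {
  cat("<env_mask_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %d cells\n", nm, sum(x[[nm]]$values)))
  }
  invisible(x)
}

#' Default transport-mode tag queries
#'
#' Per transport mode, the `(key, value)` tag filters that select network
#' polylines for that mode. Defaults follow the usual qualitative rules: the
#' in-car environment spans the major road network including motorways, buses
#' run on major roads but not motorways, walking uses foot infrastructure and
#' living streets, cycling uses designated cycleways, and the three rail
#' environments pick their respective railway tags. Fully editable — pass your
#' own table to override.
#'
#' @return A tibble with columns `mode`, `key`, `value`.
#' @export
default_mode_queries <- function() {
  tibble::tribble(
    ~mode,             ~key,      ~value,
    "walking",         "highway", "footway",
    "walking",         "highway", "path",
    "walking",         "highway", "pedestrian",
    "walking",         "highway", "living_street",
    "cycling",         "highway", "cycleway",
    "in_car",          "highway", "motorway",
    "in_car",          "highway", "trunk",
    "in_car",          "highway", "primary",
    "in_car",          "highway", "secondary",
    "buses",           "highway", "trunk",
    "buses",           "highway", "primary",
    "buses",           "highway", "secondary",
    "subway_trains",   "railway", "subway",
    "suburban_trains", "railway", "light_rail",
    "regional_trains", "railway", "rail"
  )
}

#' Select the network polylines belonging to one transport mode
#'
#' Returns exactly the polylines whose `(key, value)` tag matches any
#' configured filter for the mode.
#'
#' @param network Tibble of tagged polylines with columns `key`, `value` and a
#'   `geometry` list-column (e.g. from [read_geojson_lines()]).
#' @param mode A transport-mode id, see [transport_modes()].
#' @param queries Tag-filter table, see [default_mode_queries()].
#' @return The matching subset of `network`.
#' @export
select_mode_links <- function(network, mode, queries = default_mode_queries()) {
  check_environment(mode, transport_modes())
  q <- queries[queries$mode == mode, , drop = FALSE]
  if (nrow(q) == 0) {
    stop(sprintf("no tag filters configured for mode '%s'", mode), call. = FALSE)
  }
  if (nrow(network) == 0) return(network)
  keep <- rep(FALSE, nrow(network))
  for (i in seq_len(nrow(q))) {
    keep <- keep | (network$key == q$key[i] & network$value == q$value[i])
  }
  network[keep, , drop = FALSE]
}

#' Build the seven transport-mode masks from a tagged network
#'
#' For each mode, [select_mode_links()] picks the polylines and
#' [rasterize_polylines()] marks the covered cells. Masks may overlap: one
#' street can host walking, cycling, cars and buses at once.
#'
#' @inheritParams select_mode_links
#' @param grid A [make_grid()] grid.
#' @return An `env_mask_set` of seven logical masks.
#' @export
build_transport_environments <- function(network, queries = default_mode_queries(),
                                         grid) {
  masks <- lapply(transport_modes(), function(mode) {
    sub <- select_mode_links(network, mode, queries)
    rasterize_polylines(sub, grid, name = mode)
  })
  names(masks) <- transport_modes()
  structure(masks, grid = grid, class = "env_mask_set")
}
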