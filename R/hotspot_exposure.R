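#' Rasterize species hotspots onto the analysis grid
#'
#' A cell belongs to a species when any of its polygons intersects the
#' cell (default), or contains the cell centre (`rule = "centre"`). Each
#' species gets two role masks: the sea-role mask keeps intersected cells
#' classed `sea` or `mixed`, the land-role mask keeps `land` or `mixed` —
#' the per-event-type routing rule for coastal pixels. A small island
#' polygon lying inside a sea-classed cell therefore has an empty
#' land-role mask, and the species' land metrics are reported missing.
#'
#' @param hotspots A `hotspot_set` (from [generate_hotspots()] or
#'   [read_hotspots_geojson()]).
#' @param grid A [grid_def()].
#' @param rule Cell membership rule: `"intersect"` (default) or
#'   `"centre"`.
#' @return An object of class `hotspot_masks`: per species a list with
#'   logical matrices `cells`, `sea` and `land`, plus the species' `iucn`
#'   label.
#' @export
rasterize_hotspots <- function(hotspots, grid,
                               rule = c("intersect", "centre")) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  assert_grid_def(grid)
  rule <- match.arg(rule)
  nm <- vapply(hotspots$species, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("species names must be unique")
  sea_role <- surface_mask(grid, "sea")
  land_role <- surface_mask(grid, "land")
  masks <- lapply(hotspots$species, function(s) {
    for (ring in s$polygons) {
      if (!is.matrix(ring) || nrow(ring) < 3 || ring_area(ring) == 0 ||
          ring_self_intersects(ring))
        stop("invalid polygon geometry for species '", s$name, "'")
    }
    cells <- matrix(FALSE, grid$nlat, grid$nlon)
    for (ring in s$polygons) {
      rx <- range(ring[, 1]); ry <- range(ring[, 2])
      js <- which(grid$lon_edges[-1] >= rx[1] &
                    grid$lon_edges[-(grid$nlon + 1)] <= rx[2])
      is <- which(grid$lat_edges[-1] >= ry[1] &
                    grid$lat_edges[-(grid$nlat + 1)] <= ry[2])
      for (j in js) for (i in is) {
        if (cells[i, j]) next
        if (rule == "centre") {
          cells[i, j] <- point_in_ring(grid$lon_centers[j],
                                       grid$lat_centers[i], ring)
        } else {
          cells[i, j] <- ring_intersects_cell(
            ring, grid$lon_edges[j], grid$lon_edges[j + 1],
            grid$lat_edges[i], grid$lat_edges[i + 1])
        }
      }
    }
    if (!any(cells))
      message("hotspot '", s$name, "' does not overlap the grid: empty mask")
    list(name = s$name, iucn = s$iucn %||% NA_character_, cells = cells,
         sea = cells & sea_role, land = cells & land_role)
  })
  names(masks) <- nm
  structure(list(species = masks, grid = grid, rule = rule),
            class = "hotspot_masks")
}

#' @export
print.hotspot_masks <- function(x, ...) {
  cat(sprintf("<hotspot_masks> %d species (%s rule)\n",
              length(x$species), x$rule))
  for (s in x$species)
    cat(sprintf("  %s: %d cells (%d sea-role, %d land-role)\n",
                s$name, sum(s$cells), sum(s$sea), sum(s$land)))
  invisible(x)
}

#' Species mean exposure to extreme-event metrics
#'
#' For each species and event type: the mean metric value over the
#' species' environment-role cells (non-missing pixels only); the
#' cumulative value (sum of those means across event types); and each
#' type's relative contribution to the cumulative sum. Species with an
#' empty role mask get missing rows.
#'
#' @param layers List of [metric_layer()]s, one per event type of one
#'   environment, sharing a metric (raw units, not normalized).
#' @param masks A [rasterize_hotspots()] object.
#' @param environment `"sea"` or `"land"`.
#' @return A tidy [tibble::tibble]: one row per species x event type with
#'   `mean_value`, `cumulative` and `contribution`.
#' @export
species_mean_exposure <- function(layers, masks,
                                  environment = c("sea", "land")) {
  environment <- match.arg(environment)
  stopifnot(inherits(masks, "hotspot_masks"))
  allowed <- event_types(environment)
  types <- vapply(layers, function(l) l$event_type, "")
  layers <- layers[order(match(types, allowed))]
  types <- vapply(layers, function(l) l$event_type, "")
  if (!all(types %in% allowed))
    stop("layer event types do not belong to the ", environment,
         " environment")
  metric <- unique(vapply(layers, function(l) l$metric, ""))
  if (length(metric) != 1) stop("layers mix metrics")
  rows <- lapply(masks$species, function(s) {
    m <- s[[environment]]
    if (!any(m)) {
      message("species '", s$name, "': empty ", environment,
              "-role mask, reporting missing values")
      means <- rep(NA_real_, length(types))
    } else {
      means <- vapply(layers, function(l) {
        v <- l$values[m]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, 0)
    }
    cum <- if (all(is.na(means))) NA_real_ else sum(means, na.rm = TRUE)
    contrib <- if (is.na(cum) || cum == 0) rep(NA_real_, length(means))
               else means / cum
    tibble::tibble(species = s$name, iucn = s$iucn,
                   environment = environment, metric = metric,
                   event_type = types, mean_value = means,
                   cumulative = cum, contribution = contrib)
  })
  do.call(rbind, rows)
}

#' Normalize species cumulative values by the group maximum
#'
#' Divides each species' cumulative value by the largest cumulative value
#' across species within its metric x environment group, so the most
#' exposed species scores 1 and all others fall in (0, 1]. Groups whose
#' cumulatives are all missing are skipped.
#'
#' @param table Output of [species_mean_exposure()] or
#'   [species_trend_exposure()] (any tibble with `metric`, `environment`
#'   and `cumulative` columns).
#' @return The table with a `norm_cumulative` column appended.
#' @export
normalize_species <- function(table) {
  stopifnot(all(c("metric", "environment", "cumulative") %in% names(table)))
  table$norm_cumulative <- NA_real_
  groups <- unique(table[, c("metric", "environment")])
  for (k in seq_len(nrow(groups))) {
    sel <- table$metric == groups$metric[k] &
      table$environment == groups$environment[k]
    cums <- table$cumulative[sel]
    if (all(is.na(cums))) {
      message("group ", groups$metric[k], "/", groups$environment[k],
              ": all cumulatives missing, skipped")
      next
    }
    mx <- max(cums, na.rm = TRUE)
    if (mx == 0) next
    table$norm_cumulative[sel] <- cums / mx
  }
  table
}

#' Species exposure to positive-and-significant trends
#'
#' For each species and event type: the mean retained slope over the
#' species' environment-role cells (0 when no cell is retained), adjusted
#' by dividing by the species' *total* role-mask cell count — shrinking
#' the value for species whose hotspot is mostly trend-free — and the
#' coverage percentage of retained cells, per type and as the union
#' across types. The cumulative trend value is the sum of adjusted means;
#' contributions are their fractions of that sum.
#'
#' @param layers List of [filter_positive_significant()] trend layers of
#'   one environment and metric.
#' @param masks A [rasterize_hotspots()] object.
#' @param environment `"sea"` or `"land"`.
#' @return A tidy [tibble::tibble]: one row per species x event type with
#'   `n_cells`, `n_retained`, `mean_slope`, `adjusted_mean`,
#'   `coverage_pct`, `coverage_union_pct`, `cumulative`, `contribution`.
#' @export
species_trend_exposure <- function(layers, masks,
                                   environment = c("sea", "land")) {
  environment <- match.arg(environment)
  stopifnot(inherits(masks, "hotspot_masks"))
  if (!all(vapply(layers, function(l) isTRUE(l$filtered), TRUE)))
    stop("layers must pass through filter_positive_significant() first")
  allowed <- event_types(environment)
  types <- vapply(layers, function(l) l$event_type, "")
  layers <- layers[order(match(types, allowed))]
  types <- vapply(layers, function(l) l$event_type, "")
  metric <- unique(vapply(layers, function(l) l$metric, ""))
  if (length(metric) != 1) stop("layers mix metrics")
  rows <- lapply(masks$species, function(s) {
    m <- s[[environment]]
    n_total <- sum(m)
    if (n_total == 0) {
      message("species '", s$name, "': empty ", environment,
              "-role mask, reporting missing values")
      return(tibble::tibble(
        species = s$name, iucn = s$iucn, environment = environment,
        metric = metric, event_type = types, n_cells = 0L,
        n_retained = NA_integer_, mean_slope = NA_real_,
        adjusted_mean = NA_real_, coverage_pct = NA_real_,
        coverage_union_pct = NA_real_, cumulative = NA_real_,
        contribution = NA_real_))
    }
    union_ret <- matrix(FALSE, nrow(m), ncol(m))
    n_ret <- integer(length(types))
    mean_slope <- numeric(length(types))
    for (k in seq_along(layers)) {
      ret <- layers[[k]]$retained & m
      union_ret <- union_ret | ret
      n_ret[k] <- sum(ret)
      mean_slope[k] <- if (n_ret[k] == 0) 0 else
        mean(layers[[k]]$slope[ret])
    }
    adjusted <- mean_slope / n_total
    cum <- sum(adjusted)
    contrib <- if (cum > 0) adjusted / cum else rep(NA_real_, length(adjusted))
    tibble::tibble(
      species = s$name, iucn = s$iucn, environment = environment,
      metric = metric, event_type = types, n_cells = n_total,
      n_retained = n_ret, mean_slope = mean_slope,
      adjusted_mean = adjusted,
      coverage_pct = 100 * n_ret / n_total,
      coverage_union_pct = 100 * sum(union_ret & m) / n_total,
      cumulative = cum, contribution = contrib)
  })
  do.call(rbind, rows)
}
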