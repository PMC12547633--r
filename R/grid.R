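#' Define a regular latitude/longitude analysis grid
#'
#' Builds the regular grid on which all detection and stacking operates.
#' Each cell carries a surface class: `"land"`, `"sea"` or `"mixed"`
#' (coastal cells containing both). Mixed cells participate in both the
#' sea-role and the land-role masks, so sea-based and land-based events
#' are evaluated on the appropriate side of the coast.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid edges in degrees. Longitudes
#'   use the `[-180, 180)` convention.
#' @param cell_size Cell size in degrees (default 1).
#' @param surface Optional character matrix `nlat x nlon` with values in
#'   `c("land", "sea", "mixed")`; defaults to all-`"sea"`.
#' @return An object of class `grid_def`.
#' @examples
#' g <- grid_def(-10, 0, 0, 10)
#' g$nlat
#' @export
grid_def <- function(lat_min, lat_max, lon_min, lon_max, cell_size = 1,
                     surface = NULL) {
  stopifnot(is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(lon_min), is.numeric(lon_max), cell_size > 0)
  if (lat_max <= lat_min) stop("lat_max must exceed lat_min")
  if (lon_max <= lon_min) stop("lon_max must exceed lon_min")
  if (lon_min < -180 || lon_max > 180)
    stop("longitudes must lie in [-180, 180]")
  nlat <- (lat_max - lat_min) / cell_size
  nlon <- (lon_max - lon_min) / cell_size
  if (abs(nlat - round(nlat)) > 1e-8 || abs(nlon - round(nlon)) > 1e-8)
    stop("grid extent must be a whole number of cells")
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  lat_edges <- lat_min + cell_size * (0:nlat)
  lon_edges <- lon_min + cell_size * (0:nlon)
  if (is.null(surface)) {
    surface <- matrix("sea", nlat, nlon)
  } else {
    surface <- as.matrix(surface)
    if (!all(dim(surface) == c(nlat, nlon)))
      stop("surface must be a ", nlat, " x ", nlon, " matrix")
    if (!all(surface %in% c("land", "sea", "mixed")))
      stop("surface classes must be 'land', 'sea' or 'mixed'")
  }
  structure(list(
    lat_edges = lat_edges, lon_edges = lon_edges,
    lat_centers = (lat_edges[-1] + lat_edges[-(nlat + 1)]) / 2,
    lon_centers = (lon_edges[-1] + lon_edges[-(nlon + 1)]) / 2,
    nlat = nlat, nlon = nlon, cell_size = cell_size,
    surface = surface
  ), class = "grid_def")
}

#' @export
print.grid_def <- function(x, ...) {
  cat(sprintf("<grid_def> %d x %d cells of %g deg, lat [%g, %g], lon [%g, %g]\n",
              x$nlat, x$nlon, x$cell_size,
              min(x$lat_edges), max(x$lat_edges),
              min(x$lon_edges), max(x$lon_edges)))
  tab <- table(factor(x$surface, levels = c("land", "sea", "mixed")))
  cat("  surface:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Environment-role mask of a grid
#'
#' Sea-role cells are those classed `sea` or `mixed`; land-role cells are
#' `land` or `mixed`. Coastal (`mixed`) cells therefore belong to both
#' roles.
#'
#' @param grid A [grid_def()].
#' @param role `"sea"` or `"land"`.
#' @return Logical `nlat x nlon` matrix.
#' @export
surface_mask <- function(grid, role = c("sea", "land")) {
  role <- match.arg(role)
  keep <- if (role == "sea") c("sea", "mixed") else c("land", "mixed")
  matrix(grid$surface %in% keep, grid$nlat, grid$nlon)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lat_edges, b$lat_edges)) &&
    isTRUE(all.equal(a$lon_edges, b$lon_edges))
}

assert_grid_def <- function(grid) {
  if (!inherits(grid, "grid_def")) stop("expected a 'grid_def' object")
  if (grid$nlat < 1 || grid$nlon < 1) stop("degenerate grid: no cells")
  invisible(grid)
}
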