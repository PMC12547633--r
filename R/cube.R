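#' Daily gridded field cube
#'
#' Container for one variable's daily values on a regular lat/lon grid.
#' Time is a contiguous sequence of day indices `1..nt` on a 365-day
#' (no-leap) calendar: day `t` falls on calendar day `(t-1) %% 365 + 1` of
#' year `(t-1) %/% 365 + 1`.
#'
#' @param values Numeric array `c(nt, nlat, nlon)`; `NA` marks cells where
#'   the variable is undefined (e.g. SST over land).
#' @param grid A [grid_def()].
#' @param variable_kind One of `"sst"`, `"air_temp"`, `"wind_u"`,
#'   `"wind_v"`, `"wind"`, `"precip"`.
#' @param units Units label (`"degC"`, `"m/s"`, `"m/h"`, ...).
#' @return An object of class `daily_cube`.
#' @export
daily_cube <- function(values, grid, variable_kind, units) {
  assert_grid_def(grid)
  variable_kind <- match.arg(variable_kind, VARIABLE_KINDS)
  if (length(dim(values)) != 3)
    stop("values must be a 3-d array (time, lat, lon)")
  if (dim(values)[2] != grid$nlat || dim(values)[3] != grid$nlon)
    stop("values spatial dimensions do not match the grid")
  structure(list(
    values = values, grid = grid, variable_kind = variable_kind,
    units = units, nt = dim(values)[1]
  ), class = "daily_cube")
}

#' @export
print.daily_cube <- function(x, ...) {
  cat(sprintf("<daily_cube> %s [%s], %d days (%.2f yr) on %dx%d grid\n",
              x$variable_kind, x$units, x$nt, x$nt / DAYS_PER_YEAR,
              x$grid$nlat, x$grid$nlon))
  invisible(x)
}

cube_doy <- function(t) (t - 1L) %% DAYS_PER_YEAR + 1L
cube_year <- function(t) (t - 1L) %/% DAYS_PER_YEAR + 1L

cube_n_years <- function(cube) {
  ny <- cube$nt / DAYS_PER_YEAR
  if (abs(ny - round(ny)) > 1e-9)
    stop("cube does not span whole 365-day years")
  as.integer(round(ny))
}

#' Write a daily cube to a portable text file
#'
#' The format is a one-line JSON header (prefixed `#cumulex-cube `)
#' describing the variable, units and grid, followed by a CSV body with a
#' `day` column and one column per grid cell. Doubles are written with 17
#' significant digits so values round-trip exactly.
#'
#' @param cube A [daily_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "daily_cube"))
  g <- cube$grid
  header <- jsonlite::toJSON(list(
    format = "cumulex-cube", version = 1L,
    variable_kind = cube$variable_kind, units = cube$units,
    nt = cube$nt, nlat = g$nlat, nlon = g$nlon,
    lat_edges = g$lat_edges, lon_edges = g$lon_edges,
    cell_size = g$cell_size, surface = as.vector(g$surface)
  ), auto_unbox = TRUE, digits = NA)
  vals <- cube$values
  dim(vals) <- c(cube$nt, g$nlat * g$nlon)
  body <- matrix(sprintf("%.17g", vals), nrow = cube$nt)
  body[is.na(vals)] <- "NA"
  dt <- data.table::as.data.table(body)
  data.table::setnames(dt, sprintf("cell_%06d", seq_len(ncol(body))))
  dt <- cbind(data.table::data.table(day = seq_len(cube$nt)), dt)
  con <- file(path, "w")
  writeLines(paste0("#cumulex-cube ", header), con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a daily cube from its text form
#'
#' Validates that the file holds the requested variable on a contiguous
#' daily axis, and converts temperatures stored in kelvin to degrees
#' Celsius.
#'
#' @param path File written by [write_cube()] (or following its format).
#' @param variable_kind Expected variable; `NULL` accepts whatever the
#'   file holds.
#' @return A [daily_cube()].
#' @export
read_cube <- function(path, variable_kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#cumulex-cube "))
    stop("not a cumulex cube file (missing header): ", path)
  hdr <- jsonlite::fromJSON(sub("^#cumulex-cube ", "", first))
  if (!is.null(variable_kind) && !identical(hdr$variable_kind, variable_kind))
    stop("file holds variable '", hdr$variable_kind,
         "', not the requested '", variable_kind, "'")
  dt <- data.table::fread(path, skip = 1L, header = TRUE, na.strings = "NA")
  if (!"day" %in% names(dt)) stop("cube file lacks a 'day' (time) axis")
  day <- dt$day
  if (length(day) != hdr$nt || !identical(as.integer(day), seq_len(hdr$nt)))
    stop("time axis is not a contiguous daily sequence")
  vals <- as.matrix(dt[, -1])
  if (ncol(vals) != hdr$nlat * hdr$nlon)
    stop("cube file body does not match its declared grid")
  dim(vals) <- c(hdr$nt, hdr$nlat, hdr$nlon)
  grid <- grid_def(hdr$lat_edges[1], hdr$lat_edges[hdr$nlat + 1],
                   hdr$lon_edges[1], hdr$lon_edges[hdr$nlon + 1],
                   cell_size = hdr$cell_size,
                   surface = matrix(hdr$surface, hdr$nlat, hdr$nlon))
  units <- hdr$units
  if (hdr$variable_kind %in% c("sst", "air_temp") &&
      units %in% c("K", "kelvin", "Kelvin")) {
    vals <- vals - 273.15
    units <- "degC"
  }
  daily_cube(vals, grid, hdr$variable_kind, units)
}

#' Bilinear regridding onto a target grid
#'
#' Interpolates each day's field at the target cell centres from the four
#' surrounding source cell centres. Missing source cells propagate missing
#' (no extrapolation across a coastline), and target centres outside the
#' source-centre hull are missing.
#'
#' @param cube Source [daily_cube()].
#' @param target Target [grid_def()] (typically the 1-degree analysis grid).
#' @return A [daily_cube()] on `target`.
#' @export
regrid_bilinear <- function(cube, target) {
  stopifnot(inherits(cube, "daily_cube"))
  assert_grid_def(target)
  src <- cube$grid
  if (grids_identical(src, target)) return(cube)
  slat <- src$lat_centers; slon <- src$lon_centers
  tlat <- target$lat_centers; tlon <- target$lon_centers
  inside_lat <- tlat >= slat[1] & tlat <= slat[length(slat)]
  inside_lon <- tlon >= slon[1] & tlon <= slon[length(slon)]
  if (!any(inside_lat) || !any(inside_lon))
    stop("source and target grids do not overlap")
  ns_lat <- length(slat); ns_lon <- length(slon)
  ilat <- pmin(pmax(findInterval(tlat, slat), 1L), ns_lat - 1L)
  ilon <- pmin(pmax(findInterval(tlon, slon), 1L), ns_lon - 1L)
  wlat <- (tlat - slat[ilat]) / (slat[ilat + 1L] - slat[ilat])
  wlon <- (tlon - slon[ilon]) / (slon[ilon + 1L] - slon[ilon])

  np_t <- target$nlat * target$nlon
  ti <- rep(seq_len(target$nlat), times = target$nlon)   # lat index per flat cell
  tj <- rep(seq_len(target$nlon), each = target$nlat)
  i0 <- ilat[ti]; j0 <- ilon[tj]
  wy <- wlat[ti]; wx <- wlon[tj]
  flat <- function(i, j) i + (j - 1L) * src$nlat
  vals <- cube$values
  dim(vals) <- c(cube$nt, src$nlat * src$nlon)
  out <- sweep(vals[, flat(i0, j0), drop = FALSE],       2, (1 - wy) * (1 - wx), "*") +
         sweep(vals[, flat(i0 + 1L, j0), drop = FALSE],  2, wy * (1 - wx), "*") +
         sweep(vals[, flat(i0, j0 + 1L), drop = FALSE],  2, (1 - wy) * wx, "*") +
         sweep(vals[, flat(i0 + 1L, j0 + 1L), drop = FALSE], 2, wy * wx, "*")
  outside <- !(inside_lat[ti] & inside_lon[tj])
  if (any(outside)) out[, outside] <- NA_real_
  dim(out) <- c(cube$nt, target$nlat, target$nlon)
  daily_cube(out, target, cube$variable_kind, cube$units)
}

#' Wind speed from u and v components
#'
#' @param u,v [daily_cube()]s of the zonal and meridional 10 m wind
#'   components (m/s) on the same grid and time axis.
#' @return A [daily_cube()] of wind speed `sqrt(u^2 + v^2)` (m/s), with
#'   `variable_kind = "wind"`.
#' @export
wind_speed <- function(u, v) {
  stopifnot(inherits(u, "daily_cube"), inherits(v, "daily_cube"))
  if (u$nt != v$nt) stop("u and v time axes differ")
  if (!grids_identical(u$grid, v$grid)) stop("u and v grids differ")
  daily_cube(sqrt(u$values^2 + v$values^2), u$grid, "wind", "m/s")
}

#' Derive a land/sea surface classification from SST missingness
#'
#' Cells where SST is missing on every day are classed `land`; all others
#' `sea`. Useful when no static mask accompanies the data; coastal `mixed`
#' cells cannot be recovered this way and must come from a real mask.
#'
#' @param sst A [daily_cube()] with `variable_kind = "sst"`.
#' @return A [grid_def()] equal to the cube's grid with updated surface.
#' @export
derive_surface <- function(sst) {
  stopifnot(inherits(sst, "daily_cube"))
  vals <- sst$values
  dim(vals) <- c(sst$nt, sst$grid$nlat * sst$grid$nlon)
  all_na <- colSums(!is.na(vals)) == 0
  g <- sst$grid
  g$surface <- matrix(ifelse(all_na, "land", "sea"), g$nlat, g$nlon)
  g
}
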