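#' Build a synthetic set of species hotspot polygons
#'
#' Generates `n_species` named polygons on the grid with the structural
#' variety the exposure stage must handle: always one coastal polygon
#' spanning both land- and sea-classed cells and one strictly marine
#' polygon; from three species up, one sub-cell "islet" polygon smaller
#' than a single grid cell and sitting inside a sea-classed cell, so its
#' land-role rasterization is empty (a colony on an island too small to
#' resolve at the grid resolution). Additional species are seeded random
#' rectangles, some split into two polygons to emulate separate breeding
#' and non-breeding ranges merged into year-round use.
#'
#' @param grid A [grid_def()] whose surface contains both land and sea
#'   cells (otherwise rejected as degenerate).
#' @param n_species Number of species (>= 1).
#' @param seed Integer seed; identical seeds give identical polygon sets.
#' @return An object of class `hotspot_set`: a list with element
#'   `species`, each entry holding `name`, `iucn` and `polygons` (a list
#'   of `n x 2` lon/lat rings).
#' @export
generate_hotspots <- function(grid, n_species, seed = 1L) {
  assert_grid_def(grid)
  if (n_species < 1) stop("n_species must be >= 1")
  surf <- grid$surface
  cs <- grid$cell_size
  has_land <- any(surf == "land"); has_sea <- any(surf == "sea")
  if (!has_land || !has_sea)
    stop("degenerate grid: hotspot generation needs both land and sea cells")

  cell_bbox <- function(i, j) {
    c(xmin = grid$lon_edges[j], xmax = grid$lon_edges[j + 1],
      ymin = grid$lat_edges[i], ymax = grid$lat_edges[i + 1])
  }
  # coastal pair: the closest land/sea cell pair (mixed cells may lie
  # between); the coastal polygon spans from one to the other
  land_cells <- which(surf == "land", arr.ind = TRUE)
  sea_cells_all <- which(surf == "sea", arr.ind = TRUE)
  d2 <- outer(seq_len(nrow(land_cells)), seq_len(nrow(sea_cells_all)),
              function(a, b) {
                pmax(abs(land_cells[a, 1] - sea_cells_all[b, 1]),
                     abs(land_cells[a, 2] - sea_cells_all[b, 2]))
              })
  best <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  pair <- list(land = land_cells[best[1], ], sea = sea_cells_all[best[2], ])
  b1 <- cell_bbox(pair$land[1], pair$land[2])
  b2 <- cell_bbox(pair$sea[1], pair$sea[2])
  pad <- 0.2 * cs
  coastal <- rect_ring(min(b1["xmin"], b2["xmin"]) + pad,
                       max(b1["xmax"], b2["xmax"]) - pad,
                       min(b1["ymin"], b2["ymin"]) + pad,
                       max(b1["ymax"], b2["ymax"]) - pad)

  sea_cells <- which(surf == "sea", arr.ind = TRUE)
  # marine polygon: inside a single sea cell, away from non-sea cells
  only_sea <- sea_cells[order(sea_cells[, 1], sea_cells[, 2]), , drop = FALSE]
  pick_sea <- only_sea[nrow(only_sea), ]  # a deterministic sea cell
  bs <- cell_bbox(pick_sea[1], pick_sea[2])
  marine <- rect_ring(bs["xmin"] + pad, bs["xmax"] - pad,
                      bs["ymin"] + pad, bs["ymax"] - pad)

  species <- list(
    list(name = "species_coastal", polygons = list(coastal)),
    list(name = "species_marine", polygons = list(marine))
  )
  if (n_species >= 3) {
    pick2 <- only_sea[1, ]  # another sea cell for the islet
    bi <- cell_bbox(pick2[1], pick2[2])
    cx <- (bi["xmin"] + bi["xmax"]) / 2; cy <- (bi["ymin"] + bi["ymax"]) / 2
    islet <- rect_ring(cx - 0.15 * cs, cx + 0.15 * cs,
                       cy - 0.15 * cs, cy + 0.15 * cs)
    species[[3]] <- list(name = "species_islet", polygons = list(islet))
  }
  n_extra <- n_species - length(species)
  if (n_extra > 0) {
    extras <- withr::with_seed(seed, {
      lapply(seq_len(n_extra), function(k) {
        n_poly <- if (runif(1) < 0.5) 2L else 1L  # two ranges to merge
        polys <- lapply(seq_len(n_poly), function(q) {
          w <- runif(1, 1.2, 3.5) * cs; h <- runif(1, 1.2, 3.5) * cs
          x0 <- runif(1, min(grid$lon_edges), max(grid$lon_edges) - w)
          y0 <- runif(1, min(grid$lat_edges), max(grid$lat_edges) - h)
          rect_ring(x0, x0 + w, y0, y0 + h)
        })
        list(name = sprintf("species_%02d", k + 3L), polygons = polys)
      })
    }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
       .rng_sample_kind = "Rejection")
    species <- c(species, extras)
  }
  species <- species[seq_len(n_species)]
  iucn <- c("EN", "LC", "CR", "VU", "NT")
  for (k in seq_along(species))
    species[[k]]$iucn <- iucn[(k - 1L) %% length(iucn) + 1L]
  structure(list(species = species, grid = grid), class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> %d species\n", length(x$species)))
  for (s in x$species)
    cat(sprintf("  %s [%s]: %d polygon(s)\n", s$name, s$iucn %||% "?",
                length(s$polygons)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write hotspots as a GeoJSON FeatureCollection
#'
#' One feature per species, geometry `MultiPolygon`, with `species` and
#' `iucn` properties.
#'
#' @param hotspots A `hotspot_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_geojson <- function(hotspots, path) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  features <- lapply(hotspots$species, function(s) {
    coords <- lapply(s$polygons, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      list(lapply(seq_len(nrow(closed)),
                  function(i) c(closed[i, 1], closed[i, 2])))
    })
    list(type = "Feature",
         properties = list(species = s$name, iucn = s$iucn %||% NA),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read hotspots from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` features carrying a `species`
#' property (optional `iucn`). Features sharing a species name are merged
#' into one species (year-round habitat use from separate seasonal
#' ranges). Only outer rings are used.
#'
#' @param path GeoJSON file.
#' @return A `hotspot_set` (without a grid; rasterization supplies one).
#' @export
read_hotspots_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  ring_of <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  sp <- list()
  for (f in fc$features) {
    name <- f$properties$species
    if (is.null(name)) stop("feature lacks a 'species' property")
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(ring_of(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(p) ring_of(p[[1]])),
      stop("unsupported geometry type: ", geom$type))
    if (is.null(sp[[name]])) {
      sp[[name]] <- list(name = name,
                         iucn = f$properties$iucn %||% NA_character_,
                         polygons = rings)
    } else {
      sp[[name]]$polygons <- c(sp[[name]]$polygons, rings)
    }
  }
  structure(list(species = unname(sp), grid = NULL), class = "hotspot_set")
}
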