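hotspots_from_rings <- function(rings_by_species) {
  structure(list(species = lapply(names(rings_by_species), function(nm) {
    list(name = nm, iucn = "LC", polygons = rings_by_species[[nm]])
  }), grid = NULL), class = "hotspot_set")
}

rect <- function(x0, x1, y0, y1) {
  cbind(lon = c(x0, x1, x1, x0), lat = c(y0, y0, y1, y1))
}

test_that("a polygon covering one sea cell rasterizes to that cell only", {
  g <- coastal_grid(4, 4, n_land = 1, n_mixed = 0, lat0 = -4, lon0 = 0)
  # cell (2, 3): lat [-3,-2], lon [2,3] -- sea-classed
  hs <- hotspots_from_rings(list(one = list(rect(2.2, 2.8, -2.8, -2.2))))
  mk <- rasterize_hotspots(hs, g)
  expect_equal(sum(mk$species$one$cells), 1)
  expect_true(mk$species$one$cells[2, 3])
  expect_equal(sum(mk$species$one$sea), 1)
  expect_equal(sum(mk$species$one$land), 0)
})

test_that("rasterization matches the exact rectangle-overlap oracle", {
  g <- sea_grid(6, 6, lat0 = -6, lon0 = 0)
  rects <- withr::with_seed(19, lapply(1:8, function(k) {
    x0 <- runif(1, -1, 5); y0 <- runif(1, -7, -1)
    c(x0, x0 + runif(1, 0.3, 3), y0, y0 + runif(1, 0.3, 3))
  }))
  rings <- lapply(rects, function(r) list(rect(r[1], r[2], r[3], r[4])))
  names(rings) <- sprintf("sp%02d", 1:8)
  mk <- rasterize_hotspots(hotspots_from_rings(rings), g)
  for (k in 1:8) {
    r <- rects[[k]]
    for (i in 1:6) for (j in 1:6) {
      expected <- rect_hits_cell(r[1], r[2], r[3], r[4],
                                 g$lon_edges[j], g$lon_edges[j + 1],
                                 g$lat_edges[i], g$lat_edges[i + 1])
      expect_identical(mk$species[[k]]$cells[i, j], expected)
    }
  }
})

test_that("triangles spanning cells without interior vertices still hit them", {
  g <- sea_grid(3, 3, lat0 = 0, lon0 = 0)
  # long thin triangle crossing the middle column; no vertex inside (2,2)
  tri <- cbind(lon = c(0.1, 2.9, 2.9), lat = c(1.5, 1.4, 1.6))
  mk <- rasterize_hotspots(hotspots_from_rings(list(tri = list(tri))), g)
  expect_true(mk$species$tri$cells[2, 2])
  # cell fully containing the polygon, and polygon fully containing a cell
  big <- rect(-0.5, 3.5, -0.5, 3.5)
  mk2 <- rasterize_hotspots(hotspots_from_rings(list(big = list(big))), g)
  expect_true(all(mk2$species$big$cells))
})

test_that("the centre rule is stricter than the intersect rule", {
  g <- sea_grid(4, 4, lat0 = 0, lon0 = 0)
  ring <- rect(0.6, 2.4, 0.6, 2.4)
  hs <- hotspots_from_rings(list(a = list(ring)))
  inter <- rasterize_hotspots(hs, g, rule = "intersect")$species$a$cells
  centre <- rasterize_hotspots(hs, g, rule = "centre")$species$a$cells
  expect_true(all(centre <= inter))
  expect_equal(sum(centre), 1)   # only the (1.5, 1.5) centre lies inside
  expect_equal(sum(inter), 9)    # the rectangle touches a 3 x 3 block
})

test_that("shrinking a polygon never grows its mask", {
  g <- sea_grid(5, 5, lat0 = 0, lon0 = 0)
  base <- rect(0.7, 4.1, 0.9, 4.3)
  centroid <- colMeans(base)
  shrunk <- sweep(sweep(base, 2, centroid), 1, 0.5, "*")
  shrunk <- sweep(shrunk, 2, centroid, "+")
  hs <- hotspots_from_rings(list(big = list(base), small = list(shrunk)))
  mk <- rasterize_hotspots(hs, g)
  expect_true(all(mk$species$small$cells <= mk$species$big$cells))
})

test_that("invalid geometry is rejected naming the species", {
  g <- sea_grid(3, 3)
  bowtie <- cbind(lon = c(0, 2, 0, 2), lat = c(-10, -8, -8, -10))
  hs <- hotspots_from_rings(list(bad = list(bowtie)))
  expect_error(rasterize_hotspots(hs, g), "bad")
})

test_that("species mean exposure follows the masked-mean arithmetic", {
  g <- coastal_grid(4, 4, n_land = 1, n_mixed = 1, lat0 = -4, lon0 = 0)
  # species over 5 sea cells; uniform layers
  hs <- hotspots_from_rings(list(u = list(rect(2.1, 3.9, -3.9, -1.1))))
  mk <- rasterize_hotspots(hs, g)
  mhw <- metric_layer(matrix(1, 4, 4), "MHW", "intensity", "degC", g)
  wnd <- metric_layer(matrix(3, 4, 4), "wind_sea", "intensity", "degC", g)
  tab <- species_mean_exposure(list(mhw, wnd), mk, "sea")
  expect_equal(tab$mean_value, c(1, 3))
  expect_equal(unique(tab$cumulative), 4)
  expect_equal(tab$contribution, c(0.25, 0.75))
  expect_equal(sum(tab$contribution), 1)
})

test_that("species mean exposure matches a brute-force oracle", {
  g <- sea_grid(6, 6, lat0 = -6, lon0 = 0)
  hs <- hotspots_from_rings(list(a = list(rect(0.5, 3.5, -5.5, -2.5)),
                                 b = list(rect(2.5, 5.5, -4.5, -0.5))))
  mk <- rasterize_hotspots(hs, g)
  l1 <- random_layer(g, "MHW", metric = "duration", seed = 61, units = "days")
  l2 <- random_layer(g, "wind_sea", metric = "duration", seed = 62,
                     units = "days")
  tab <- species_mean_exposure(list(l1, l2), mk, "sea")
  for (sp in c("a", "b")) {
    m <- mk$species[[sp]]$sea
    for (ly in list(l1, l2)) {
      row <- tab[tab$species == sp & tab$event_type == ly$event_type, ]
      expect_equal(row$mean_value, mean(ly$values[m], na.rm = TRUE))
    }
    rows <- tab[tab$species == sp, ]
    expect_equal(unique(rows$cumulative), sum(rows$mean_value))
    expect_equal(rows$contribution, rows$mean_value / sum(rows$mean_value))
  }
})

test_that("an empty land-role mask yields missing land rows", {
  g <- coastal_grid(4, 4, n_land = 1, n_mixed = 0, lat0 = -4, lon0 = 0)
  # islet polygon inside a sea-classed cell
  hs <- hotspots_from_rings(list(islet = list(rect(2.4, 2.6, -2.6, -2.4))))
  mk <- rasterize_hotspots(hs, g)
  hw <- metric_layer(matrix(2, 4, 4), "HW", "intensity", "degC", g)
  expect_message(tab <- species_mean_exposure(list(hw), mk, "land"),
                 "empty land-role mask")
  expect_true(all(is.na(tab$mean_value)))
  expect_true(all(is.na(tab$cumulative)))
})

test_that("group-max normalization puts exactly the top species at 1", {
  tab <- tibble::tibble(
    species = rep(c("a", "b"), 2),
    environment = rep(c("sea", "land"), each = 2),
    metric = "frequency",
    cumulative = c(2, 4, 6, 3))
  out <- normalize_species(tab)
  expect_equal(out$norm_cumulative, c(0.5, 1, 1, 0.5))
  for (env in c("sea", "land")) {
    grp <- out[out$environment == env, ]
    expect_equal(sum(grp$norm_cumulative == 1), 1)
    expect_true(all(grp$norm_cumulative <= 1))
  }
  single <- normalize_species(tab[1, ])
  expect_equal(single$norm_cumulative, 1)
})

test_that("trend exposure applies the pixel-count adjustment and coverage", {
  g <- sea_grid(5, 5, lat0 = -5, lon0 = 0)
  # mask of 10 cells (2 rows x 5 cols)
  hs <- hotspots_from_rings(list(s = list(rect(0.1, 4.9, -4.9, -3.1))))
  mk <- rasterize_hotspots(hs, g)
  expect_equal(sum(mk$species$s$sea), 10)
  slope <- matrix(NA_real_, 5, 5)
  slope[1, 1:5] <- 2   # 5 retained cells inside the mask, slope 2
  tr <- structure(list(slope = slope,
                       p_value = matrix(0.01, 5, 5),
                       n_years = matrix(20L, 5, 5), event_type = "MHW",
                       metric = "frequency", units = "days/year", grid = g,
                       filtered = TRUE, alpha = 0.05,
                       retained = !is.na(slope)), class = "trend_layer")
  tab <- species_trend_exposure(list(tr), mk, "sea")
  expect_equal(tab$mean_slope, 2)
  expect_equal(tab$adjusted_mean, 2 / 10)
  expect_equal(tab$coverage_pct, 50)
  expect_equal(tab$coverage_union_pct, 50)
})

test_that("a hotspot with no retained cells reports zero cumulative trend", {
  g <- sea_grid(4, 4, lat0 = -4, lon0 = 0)
  hs <- hotspots_from_rings(list(quiet = list(rect(0.1, 1.9, -3.9, -2.1))))
  mk <- rasterize_hotspots(hs, g)
  none <- structure(list(slope = matrix(NA_real_, 4, 4),
                         p_value = matrix(NA_real_, 4, 4),
                         n_years = matrix(20L, 4, 4), event_type = "MHW",
                         metric = "frequency", units = "days/year", grid = g,
                         filtered = TRUE, alpha = 0.05,
                         retained = matrix(FALSE, 4, 4)),
                    class = "trend_layer")
  tab <- species_trend_exposure(list(none), mk, "sea")
  expect_equal(tab$mean_slope, 0)
  expect_equal(tab$adjusted_mean, 0)
  expect_equal(tab$coverage_pct, 0)
  expect_equal(tab$cumulative, 0)
})

test_that("trend exposure matches a masked tally oracle on random inputs", {
  g <- sea_grid(6, 6, lat0 = -6, lon0 = 0)
  hs <- hotspots_from_rings(list(a = list(rect(0.2, 4.8, -5.8, -1.2))))
  mk <- rasterize_hotspots(hs, g)
  mask <- mk$species$a$sea
  layers <- list(random_filtered(g, "MHW", 71),
                 random_filtered(g, "wind_sea", 72))
  tab <- species_trend_exposure(layers, mk, "sea")
  n_total <- sum(mask)
  union <- matrix(FALSE, 6, 6)
  for (k in 1:2) {
    ret <- layers[[k]]$retained & mask
    union <- union | ret
    row <- tab[tab$event_type == layers[[k]]$event_type, ]
    ms <- if (sum(ret) == 0) 0 else mean(layers[[k]]$slope[ret])
    expect_equal(row$mean_slope, ms)
    expect_equal(row$adjusted_mean, ms / n_total)
    expect_equal(row$coverage_pct, 100 * sum(ret) / n_total)
  }
  expect_equal(unique(tab$coverage_union_pct), 100 * sum(union) / n_total)
  expect_equal(unique(tab$cumulative), sum(tab$adjusted_mean))
  if (unique(tab$cumulative) > 0)
    expect_equal(sum(tab$contribution), 1)
})
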