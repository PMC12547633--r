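test_that("annual tallies assign events to their start year in full", {
  g <- sea_grid(2, 2)
  base <- generate_daily_cube(
    field_spec("sst", g, years = 4, noise_sd = 0, ar1 = 0, seed = 1))
  clim <- daily_climatology(base, window_days = 1, smooth_days = 1)
  # one 5-day event per year at the same pixel
  eps <- do.call(rbind, lapply(0:3, function(y)
    episode_spec(1, 1, y * 365 + 100, 5, 2)))
  # plus one event spanning the year-1/year-2 boundary at another pixel
  eps <- rbind(eps, episode_spec(2, 2, 363, 6, 2))
  ct <- detect_events(inject_episodes(base, eps), clim)
  an <- annual_metrics(ct)
  expect_equal(an$frequency[, 1, 1], rep(5, 4))
  # boundary event: counted in its start year with full duration
  expect_equal(an$frequency[, 2, 2], c(6, 0, 0, 0))
  expect_equal(an$duration[1, 2, 2], 6)
  expect_true(all(is.na(an$duration[2:4, 2, 2])))
})

test_that("annual tallies match a per-year oracle on random catalogs", {
  g <- sea_grid(3, 3)
  cube <- generate_daily_cube(field_spec("sst", g, years = 4, seed = 77))
  ct <- detect_events(cube, daily_climatology(cube))
  an <- annual_metrics(ct)
  ev <- ct$events
  ev$year <- (ev$start - 1) %/% 365 + 1
  for (i in 1:3) for (j in 1:3) for (y in 1:4) {
    sel <- ev[ev$lat_idx == i & ev$lon_idx == j & ev$year == y, ]
    if (nrow(sel) == 0) {
      expect_equal(an$frequency[y, i, j], 0)
      expect_true(is.na(an$intensity[y, i, j]))
    } else {
      expect_equal(an$frequency[y, i, j], sum(sel$duration))
      expect_equal(an$intensity[y, i, j], mean(sel$mean_intensity))
      expect_equal(an$duration[y, i, j], mean(sel$duration))
    }
  }
})

make_series <- function(y_mat, g, type = "MHW") {
  # wrap a years x 1 matrix per pixel into an annual_series for testing
  ny <- nrow(y_mat)
  arr <- array(y_mat, c(ny, g$nlat, g$nlon))
  structure(list(intensity = arr, duration = arr, frequency = arr,
                 years = ny, event_type = type, units = "degC", grid = g),
            class = "annual_series")
}

test_that("OLS trends are exact on linear and constant series", {
  g <- sea_grid(1, 2)
  y <- cbind(3 + 0.2 * (1:20), rep(4, 20))
  tr <- ols_trend(make_series(y, g), "frequency", min_years = 5)
  expect_equal(tr$slope[1, 1], 0.2, tolerance = 1e-12)
  expect_equal(tr$p_value[1, 1], 0)
  expect_equal(tr$slope[1, 2], 0)
  expect_equal(tr$p_value[1, 2], 1)
})

test_that("OLS slope and p match the normal-equations oracle and lm", {
  g <- sea_grid(1, 3)
  y <- withr::with_seed(15, cbind(1 + 0.3 * (1:25) + rnorm(25),
                                  rnorm(25),
                                  5 - 0.1 * (1:25) + rnorm(25, sd = 2)))
  y[c(3, 11), 2] <- NA  # missing years at one pixel
  tr <- ols_trend(make_series(y, g), "frequency", min_years = 5)
  for (p in 1:3) {
    o <- oracle_ols(y[, p])
    expect_equal(tr$slope[1, p], o$slope, tolerance = 1e-10)
    expect_equal(tr$p_value[1, p], o$p, tolerance = 1e-10)
    fit <- summary(lm(y[, p] ~ seq_len(25)))$coefficients
    expect_equal(tr$slope[1, p], fit[2, 1], tolerance = 1e-10)
    expect_equal(tr$p_value[1, p], fit[2, 4], tolerance = 1e-10)
  }
  expect_equal(tr$n_years[1, 2], 23)
})

test_that("pixels under the minimum year count are left missing", {
  g <- sea_grid(1, 1)
  y <- matrix(c(rnorm(5), rep(NA, 15)), 20, 1)
  tr <- ols_trend(make_series(y, g), "intensity", min_years = 10)
  expect_true(is.na(tr$slope[1, 1]))
  expect_true(is.na(tr$p_value[1, 1]))
})

test_that("the positive-and-significant filter applies the stated rule", {
  g <- sea_grid(2, 2)
  tr <- structure(list(
    slope = matrix(c(-0.1, 0.1, 0.3, 0.2), 2, 2),
    p_value = matrix(c(0.001, 0.20, 0.01, NA), 2, 2),
    n_years = matrix(20L, 2, 2), event_type = "MHW", metric = "frequency",
    units = "days/year", grid = g, filtered = FALSE, alpha = NA_real_),
    class = "trend_layer")
  fl <- filter_positive_significant(tr, alpha = 0.05)
  # negative slope removed despite significance; insignificant removed;
  # missing p removed; only the positive significant pixel stays
  expect_equal(fl$retained, matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
  expect_equal(fl$slope[2, 1], NA_real_)
  expect_equal(fl$slope[1, 2], 0.3)
  # element-wise rule oracle on random layers
  set.seed(33)
  tr$slope <- matrix(rnorm(4), 2, 2)
  tr$p_value <- matrix(runif(4), 2, 2)
  fl2 <- filter_positive_significant(tr, alpha = 0.3)
  expect_equal(fl2$retained, tr$slope > 0 & tr$p_value < 0.3)
  expect_error(filter_positive_significant(tr, alpha = 0), "alpha")
})

test_that("cumulative trend equals the normalize-sum-normalize oracle", {
  g <- sea_grid(6, 6)
  l1 <- random_filtered(g, "MHW", 41)
  l2 <- random_filtered(g, "wind_sea", 42)
  ctr <- cumulative_trend(list(l1, l2), "sea")
  contrib <- function(l) {
    out <- matrix(0, 6, 6)
    s <- l$slope[l$retained]
    out[l$retained] <- (s - min(s)) / (max(s) - min(s))
    out
  }
  tot <- contrib(l1) + contrib(l2)
  expected <- (tot - min(tot)) / (max(tot) - min(tot))
  expect_equal(ctr$values, expected)
  expect_gte(min(ctr$values, na.rm = TRUE), 0)
  expect_lte(max(ctr$values, na.rm = TRUE), 1)
  # attribution is the set of retained types
  for (i in 1:6) for (j in 1:6) {
    types <- c(if (l1$retained[i, j]) "MHW",
               if (l2$retained[i, j]) "wind_sea")
    expect_identical(ctr$combination[i, j], paste(types, collapse = "+"))
  }
  both <- l1$retained & l2$retained
  if (any(both))
    expect_true(all(ctr$combination[both] == "MHW+wind_sea"))
})

test_that("an all-unretained stack yields an empty cumulative trend", {
  g <- sea_grid(3, 3)
  tr <- structure(list(slope = matrix(-1, 3, 3),
                       p_value = matrix(0.5, 3, 3),
                       n_years = matrix(20L, 3, 3), event_type = "MHW",
                       metric = "frequency", units = "days/year", grid = g,
                       filtered = FALSE, alpha = NA_real_),
                  class = "trend_layer")
  fl <- filter_positive_significant(tr, 0.05)
  ctr <- cumulative_trend(list(fl), "sea")
  expect_true(all(ctr$values == 0))
  expect_true(all(ctr$combination == ""))
  expect_true(all(ctr$n_types == 0))
})

test_that("area fractions match a set-counting oracle and partition", {
  g <- coastal_grid(6, 6, n_land = 2, n_mixed = 1)
  layers <- list(random_filtered(g, "HW", 51), random_filtered(g, "wind_land", 52),
                 random_filtered(g, "precip", 53))
  tab <- trend_area_fractions(layers, "land")
  land <- surface_mask(g, "land")
  n_land <- sum(land)
  ret <- vapply(layers, function(l) l$retained & land, land)
  n_types <- rowSums(matrix(ret, ncol = 3))
  expect_equal(tab$n_cells[tab$combination == "any"], sum(n_types > 0))
  expect_equal(tab$n_cells[tab$combination == "single"], sum(n_types == 1))
  expect_equal(tab$n_cells[tab$combination == "multiple"], sum(n_types > 1))
  expect_equal(tab$pct[tab$combination == "any"],
               100 * sum(n_types > 0) / n_land)
  # partition identity: single + multiple = any, and combos sum to any
  expect_equal(tab$pct[tab$combination == "single"] +
                 tab$pct[tab$combination == "multiple"],
               tab$pct[tab$combination == "any"])
  combos <- tab[!tab$combination %in% c("any", "single", "multiple"), ]
  expect_equal(sum(combos$n_cells), sum(n_types > 0))
  # all-empty retention: all fractions zero
  none <- lapply(layers, function(l) {
    l$retained[] <- FALSE; l$slope[] <- NA_real_; l
  })
  tab0 <- trend_area_fractions(none, "land")
  expect_true(all(tab0$pct == 0))
})
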