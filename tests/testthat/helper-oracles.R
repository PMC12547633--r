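# Shared fixtures and independent brute-force oracles.

# all-sea grid
sea_grid <- function(nlat = 5, nlon = 5, lat0 = -10, lon0 = 0, cell = 1) {
  grid_def(lat0, lat0 + nlat * cell, lon0, lon0 + nlon * cell, cell)
}

# columns of land | mixed | sea, west to east
coastal_grid <- function(nlat = 6, nlon = 6, n_land = 2, n_mixed = 1,
                         lat0 = -6, lon0 = 0) {
  surf <- matrix("sea", nlat, nlon)
  if (n_land > 0) surf[, seq_len(n_land)] <- "land"
  if (n_mixed > 0) surf[, n_land + seq_len(n_mixed)] <- "mixed"
  grid_def(lat0, lat0 + nlat, lon0, lon0 + nlon, 1, surf)
}

# cube with externally supplied values, default zero field
flat_cube <- function(grid, nt, value = 0, kind = "air_temp",
                      units = "degC") {
  daily_cube(array(value, c(nt, grid$nlat, grid$nlon)), grid, kind, units)
}

# brute-force climatology: explicit pooling, stats::quantile, explicit
# circular moving average -- written independently of the package path
oracle_climatology <- function(cube, window_days, smooth_days, percentile) {
  ny <- cube$nt / 365
  g <- cube$grid
  h <- (window_days - 1) / 2
  hs <- (smooth_days - 1) / 2
  doy_of <- rep(1:365, ny)
  sm <- function(v) {
    vapply(1:365, function(d) {
      mean(v[((d - 1 + (-hs:hs)) %% 365) + 1])
    }, 0)
  }
  thr <- array(NA_real_, c(365, g$nlat, g$nlon))
  mu <- array(NA_real_, c(365, g$nlat, g$nlon))
  for (i in seq_len(g$nlat)) for (j in seq_len(g$nlon)) {
    x <- cube$values[, i, j]
    if (all(is.na(x))) next
    raw_t <- raw_m <- numeric(365)
    for (d in 1:365) {
      wd <- ((d - 1 + (-h:h)) %% 365) + 1
      pool <- x[doy_of %in% wd]
      raw_t[d] <- unname(quantile(pool, percentile / 100, type = 7,
                                  na.rm = TRUE))
      raw_m[d] <- mean(pool, na.rm = TRUE)
    }
    thr[, i, j] <- sm(raw_t)
    mu[, i, j] <- sm(raw_m)
  }
  list(threshold = thr, seasonal_mean = mu)
}

# closed-form OLS slope/p-value from summation formulas (normal equations)
oracle_ols <- function(y, x = seq_along(y)) {
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- b / se
  list(slope = b, p = 2 * pt(-abs(t), n - 2), n = n)
}

# random metric layer over a grid (values in raw units, some NA)
random_layer <- function(grid, type, metric = "frequency", seed = 1,
                         na_frac = 0.1, units = "days/year") {
  withr::with_seed(seed, {
    v <- matrix(runif(grid$nlat * grid$nlon, 1, 9), grid$nlat, grid$nlon)
    v[runif(length(v)) < na_frac] <- NA_real_
    metric_layer(v, type, metric, units, grid)
  })
}

# random filtered trend layer (some pixels positive and significant)
random_filtered <- function(g, type, seed) {
  withr::with_seed(seed, {
    slope <- matrix(rnorm(g$nlat * g$nlon, 0.3, 0.3), g$nlat, g$nlon)
    p <- matrix(runif(g$nlat * g$nlon, 0, 0.15), g$nlat, g$nlon)
  })
  tr <- structure(list(slope = slope, p_value = p,
                       n_years = matrix(20L, g$nlat, g$nlon),
                       event_type = type, metric = "frequency",
                       units = "days/year", grid = g, filtered = FALSE,
                       alpha = NA_real_), class = "trend_layer")
  filter_positive_significant(tr, 0.05)
}

# axis-aligned rectangle intersection with a cell: exact interval test
rect_hits_cell <- function(x0, x1, y0, y1, ex0, ex1, ey0, ey1) {
  x1 >= ex0 && x0 <= ex1 && y1 >= ey0 && y0 <= ey1
}
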