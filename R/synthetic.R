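#' Specification of a synthetic daily field
#'
#' Declares the statistical structure of one generated variable: a
#' sinusoidal seasonal cycle (phase flipped across the equator, with the
#' Southern-Hemisphere peak in mid-January), stationary AR(1) noise of a
#' given marginal standard deviation, and an optional linear trend in the
#' level. Identical specs with identical seeds generate bit-identical
#' cubes.
#'
#' Per-kind defaults (used when `seasonal_amplitude`, `noise_sd`, `ar1`
#' or `mean_level` are left `NULL`) emulate broad mid-latitude conditions:
#' SST 12 +/- 4 degC with strongly persistent noise (sd 0.8, AR1 0.8);
#' air temperature 10 +/- 8 degC (sd 3, AR1 0.6); wind components around
#' 3 and 1 m/s (sd 2.5, AR1 0.5); precipitation around 2e-4 m/h
#' (sd 1.5e-4, AR1 0.3).
#'
#' @param variable_kind One of `"sst"`, `"air_temp"`, `"wind_u"`,
#'   `"wind_v"`, `"precip"`.
#' @param grid A [grid_def()].
#' @param years Number of 365-day years (default 31, a 1993-2023-length
#'   record); must be at least 2.
#' @param seasonal_amplitude Amplitude of the seasonal cycle (field units).
#' @param noise_sd Marginal (stationary) standard deviation of the AR(1)
#'   noise; must be non-negative.
#' @param ar1 Lag-1 autocorrelation of the daily noise, in `[0, 1)`.
#' @param level_trend Linear trend in the level, field units per year.
#' @param mean_level Long-term mean level (field units).
#' @param seed Integer seed; the generator is a pure function of
#'   spec + seed.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(variable_kind, grid, years = 31L,
                       seasonal_amplitude = NULL, noise_sd = NULL,
                       ar1 = NULL, level_trend = 0, mean_level = NULL,
                       seed = 1L) {
  variable_kind <- match.arg(variable_kind,
                             setdiff(VARIABLE_KINDS, "wind"))
  assert_grid_def(grid)
  defaults <- list(
    sst      = list(mean = 12,    amp = 4,    sd = 0.8,    ar1 = 0.8),
    air_temp = list(mean = 10,    amp = 8,    sd = 3,      ar1 = 0.6),
    wind_u   = list(mean = 3,     amp = 1.5,  sd = 2.5,    ar1 = 0.5),
    wind_v   = list(mean = 1,     amp = 1.0,  sd = 2.5,    ar1 = 0.5),
    precip   = list(mean = 2e-4,  amp = 1e-4, sd = 1.5e-4, ar1 = 0.3)
  )[[variable_kind]]
  if (is.null(seasonal_amplitude)) seasonal_amplitude <- defaults$amp
  if (is.null(noise_sd)) noise_sd <- defaults$sd
  if (is.null(ar1)) ar1 <- defaults$ar1
  if (is.null(mean_level)) mean_level <- defaults$mean
  years <- as.integer(years)
  if (is.na(years) || years < 2L)
    stop("invalid field spec: 'years' must be an integer >= 2")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid field spec: 'noise_sd' must be >= 0")
  if (!is.numeric(ar1) || ar1 < 0 || ar1 >= 1)
    stop("invalid field spec: 'ar1_coefficient' must lie in [0, 1)")
  if (!is.numeric(seasonal_amplitude) || seasonal_amplitude < 0)
    stop("invalid field spec: 'seasonal_amplitude' must be >= 0")
  structure(list(
    variable_kind = variable_kind, grid = grid, years = years,
    seasonal_amplitude = seasonal_amplitude, noise_sd = noise_sd,
    ar1 = ar1, level_trend = level_trend, mean_level = mean_level,
    seed = as.integer(seed)
  ), class = "field_spec")
}

# noise-free expectation: seasonal cycle + mean + trend, [nt x npix]
seasonal_expectation <- function(spec) {
  g <- spec$grid
  nt <- spec$years * DAYS_PER_YEAR
  doy <- cube_doy(seq_len(nt))
  # SH peak at calendar day 15; NH phase shifted by half a year
  lat <- rep(g$lat_centers, times = g$nlon)
  shift <- ifelse(lat < 0, 0, DAYS_PER_YEAR / 2)
  phase <- outer(doy, shift, function(d, s) cos(2 * pi * (d - 15 - s) / DAYS_PER_YEAR))
  trend <- spec$level_trend * (seq_len(nt) - 0.5) / DAYS_PER_YEAR
  spec$mean_level + spec$seasonal_amplitude * phase + trend
}

#' Generate a synthetic daily cube
#'
#' Realizes a [field_spec()]: seasonal cycle + AR(1) noise + level trend
#' on a 365-day no-leap calendar. For `"sst"`, cells classed `land` are
#' set entirely missing (the variable is undefined there), matching how
#' observational SST products behave at the coast.
#'
#' @param spec A [field_spec()].
#' @return A [daily_cube()] of `years * 365` days.
#' @examples
#' g <- grid_def(-5, 0, 0, 5)
#' cube <- generate_daily_cube(field_spec("sst", g, years = 3, seed = 42))
#' @export
generate_daily_cube <- function(spec) {
  if (!inherits(spec, "field_spec")) stop("expected a 'field_spec'")
  g <- spec$grid
  nt <- spec$years * DAYS_PER_YEAR
  npix <- g$nlat * g$nlon
  vals <- seasonal_expectation(spec)
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed, {
      eps <- matrix(rnorm(nt * npix, sd = spec$noise_sd * sqrt(1 - spec$ar1^2)),
                    nt, npix)
      eps[1, ] <- rnorm(npix, sd = spec$noise_sd)  # stationary start
      if (spec$ar1 > 0) {
        apply(eps, 2, function(e)
          as.numeric(stats::filter(e, spec$ar1, method = "recursive")))
      } else eps
    }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
       .rng_sample_kind = "Rejection")
    vals <- vals + noise
  }
  if (spec$variable_kind == "sst") {
    land <- which(as.vector(g$surface) == "land")
    if (length(land)) vals[, land] <- NA_real_
  }
  dim(vals) <- c(nt, g$nlat, g$nlon)
  units <- switch(spec$variable_kind,
                  sst = "degC", air_temp = "degC",
                  wind_u = "m/s", wind_v = "m/s", precip = "m/h")
  daily_cube(vals, g, spec$variable_kind, units)
}

#' Describe an injected extreme episode
#'
#' Ground truth for detection tests: a block of `duration` consecutive
#' days at one pixel gets `amplitude` added on top of whatever the cube
#' holds. Amplitude is therefore defined relative to the noise-free
#' seasonal expectation when injected into a noise-free cube.
#'
#' @param lat_idx,lon_idx Pixel indices on the cube's grid.
#' @param start First day-of-record index (1-based).
#' @param duration Episode length in days (>= 1).
#' @param amplitude Added value (field units).
#' @return A one-row [tibble::tibble] that can be row-bound with others.
#' @export
episode_spec <- function(lat_idx, lon_idx, start, duration, amplitude) {
  if (any(duration < 1)) stop("episode duration must be >= 1")
  tibble::tibble(lat_idx = as.integer(lat_idx), lon_idx = as.integer(lon_idx),
                 start = as.integer(start), duration = as.integer(duration),
                 amplitude = as.numeric(amplitude))
}

#' Inject extreme episodes into a cube
#'
#' @param cube A [daily_cube()].
#' @param episodes Data frame with columns `lat_idx`, `lon_idx`, `start`,
#'   `duration`, `amplitude` (rows from [episode_spec()]). Overlapping
#'   episodes at the same pixel add.
#' @return A new [daily_cube()]; the input is not modified.
#' @export
inject_episodes <- function(cube, episodes) {
  stopifnot(inherits(cube, "daily_cube"))
  if (is.null(episodes) || nrow(episodes) == 0) return(cube)
  need <- c("lat_idx", "lon_idx", "start", "duration", "amplitude")
  if (!all(need %in% names(episodes)))
    stop("episodes must have columns: ", paste(need, collapse = ", "))
  g <- cube$grid
  vals <- cube$values
  for (k in seq_len(nrow(episodes))) {
    e <- episodes[k, ]
    if (e$duration < 1) stop("episode duration must be >= 1")
    if (e$lat_idx < 1 || e$lat_idx > g$nlat || e$lon_idx < 1 || e$lon_idx > g$nlon)
      stop("episode pixel (", e$lat_idx, ",", e$lon_idx, ") outside the grid")
    last <- e$start + e$duration - 1L
    if (e$start < 1 || last > cube$nt)
      stop("episode days [", e$start, ", ", last, "] fall outside the record")
    if (anyNA(vals[e$start:last, e$lat_idx, e$lon_idx]))
      stop("episode targets a missing-valued pixel (", e$lat_idx, ",",
           e$lon_idx, ")")
    vals[e$start:last, e$lat_idx, e$lon_idx] <-
      vals[e$start:last, e$lat_idx, e$lon_idx] + e$amplitude
  }
  daily_cube(vals, g, cube$variable_kind, cube$units)
}
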