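#' Seasonally varying percentile climatology
#'
#' For every calendar day `d` (1..365) and pixel, pools the values falling
#' within `d +/- (window_days-1)/2` (circular across the year boundary)
#' from every year of the record, takes the requested percentile
#' (empirical quantile, type 7), and smooths the resulting 365-day series
#' with a centred circular moving average of length `smooth_days`. The
#' seasonal mean is computed identically with the mean in place of the
#' percentile. No detrending is performed; the full record is the
#' baseline.
#'
#' @param cube A [daily_cube()] spanning at least two full 365-day years.
#' @param window_days Odd pooling-window width in days (default 11).
#' @param smooth_days Odd smoothing width in days (default 31).
#' @param percentile Threshold percentile in (0, 100); default 90.
#' @return An object of class `climatology` with `threshold` and
#'   `seasonal_mean` arrays of shape `c(365, nlat, nlon)`.
#' @export
daily_climatology <- function(cube, window_days = 11L, smooth_days = 31L,
                              percentile = 90) {
  stopifnot(inherits(cube, "daily_cube"))
  years <- cube_n_years(cube)
  if (years < 2L) stop("record must span at least 2 full years")
  if (window_days < 1 || window_days %% 2 == 0)
    stop("window_days must be a positive odd integer")
  if (smooth_days < 1 || smooth_days %% 2 == 0)
    stop("smooth_days must be a positive odd integer")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  g <- cube$grid
  npix <- g$nlat * g$nlon
  vals <- cube$values
  dim(vals) <- c(cube$nt, npix)
  arr <- array(vals, c(DAYS_PER_YEAR, years, npix))
  half <- (window_days - 1L) / 2L
  p <- percentile / 100
  thr <- matrix(NA_real_, DAYS_PER_YEAR, npix)
  mu <- matrix(NA_real_, DAYS_PER_YEAR, npix)
  for (d in seq_len(DAYS_PER_YEAR)) {
    doys <- ((d - 1L + (-half):half) %% DAYS_PER_YEAR) + 1L
    m <- arr[doys, , , drop = FALSE]
    dim(m) <- c(window_days * years, npix)
    thr[d, ] <- col_quantile(m, p)
    cm <- colMeans(m, na.rm = TRUE)
    cm[is.nan(cm)] <- NA_real_
    mu[d, ] <- cm
  }
  thr <- smooth_circular(thr, smooth_days)
  mu <- smooth_circular(mu, smooth_days)
  dim(thr) <- c(DAYS_PER_YEAR, g$nlat, g$nlon)
  dim(mu) <- c(DAYS_PER_YEAR, g$nlat, g$nlon)
  structure(list(
    threshold = thr, seasonal_mean = mu, window_days = as.integer(window_days),
    smooth_days = as.integer(smooth_days), percentile = percentile,
    variable_kind = cube$variable_kind, units = cube$units,
    years = years, grid = g
  ), class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf(
    "<climatology> %s: p%g threshold, window %d d, smooth %d d, %d-yr baseline\n",
    x$variable_kind, x$percentile, x$window_days, x$smooth_days, x$years))
  invisible(x)
}

# column-wise empirical quantile (type 7); NA-free columns vectorized,
# others fall back to stats::quantile with na.rm
col_quantile <- function(m, p) {
  out <- rep(NA_real_, ncol(m))
  has_na <- colSums(is.na(m)) > 0
  clean <- which(!has_na)
  if (length(clean)) {
    s <- apply(m[, clean, drop = FALSE], 2, sort)
    n <- nrow(m)
    h <- (n - 1) * p + 1
    lo <- floor(h); fr <- h - lo
    q <- s[lo, ]
    if (fr > 0) q <- q + fr * (s[lo + 1, ] - q)
    out[clean] <- q
  }
  for (j in which(has_na)) {
    x <- m[, j]
    if (all(is.na(x))) next
    out[j] <- unname(quantile(x, p, type = 7, na.rm = TRUE))
  }
  out
}

smooth_circular <- function(m, k) {
  if (k <= 1) return(m)
  # sum-then-divide keeps constants exact (rep(1/k, k) does not sum to 1)
  sm <- stats::filter(m, rep(1, k), method = "convolution",
                      sides = 2, circular = TRUE)
  matrix(as.numeric(sm) / k, nrow(m), ncol(m))
}

#' Detect discrete extreme events
#'
#' An extreme event is a maximal run of days whose value strictly exceeds
#' the calendar-day threshold, kept when the run reaches the type-specific
#' minimum duration: 5 days for marine heatwaves (`MHW`), 3 days for the
#' atmospheric types (`HW`, `wind_sea`, `wind_land`, `precip`). Runs are
#' not joined across gaps by default. Each event's mean intensity is the
#' mean over its days of the anomaly relative to the seasonal mean (or to
#' the threshold, if `intensity_ref = "threshold"`).
#'
#' @param cube A [daily_cube()].
#' @param clim Matching [daily_climatology()] (same variable and grid).
#' @param event_type One of `"MHW"`, `"HW"`, `"wind_sea"`, `"wind_land"`,
#'   `"precip"`; defaults from the variable kind (wind cubes must say
#'   which side of the coast they are being analysed for).
#' @param min_duration Minimum duration in days; default 5 for `MHW`,
#'   3 otherwise.
#' @param min_rule `"geq"` keeps runs of length `>= min_duration` (the
#'   convention used here); `"gt"` keeps strictly longer runs.
#' @param pixel_mask Optional logical `nlat x nlon` matrix restricting
#'   detection (e.g. a [surface_mask()]); default all pixels with data.
#' @param join_gap Join events separated by at most this many
#'   non-exceedance days (0 = off, the default).
#' @param intensity_ref Anomaly reference: `"seasonal_mean"` (default) or
#'   `"threshold"`.
#' @return An object of class `event_catalog`: tibble `events` with
#'   columns `lat_idx`, `lon_idx`, `start`, `end`, `duration`,
#'   `mean_intensity`, plus `event_type`, `record_years`, `grid`, and the
#'   logical `pixels_valid` matrix of pixels that were searched.
#' @export
detect_events <- function(cube, clim, event_type = NULL, min_duration = NULL,
                          min_rule = c("geq", "gt"), pixel_mask = NULL,
                          join_gap = 0L,
                          intensity_ref = c("seasonal_mean", "threshold")) {
  stopifnot(inherits(cube, "daily_cube"), inherits(clim, "climatology"))
  min_rule <- match.arg(min_rule)
  intensity_ref <- match.arg(intensity_ref)
  if (!grids_identical(cube$grid, clim$grid))
    stop("cube and climatology grids differ")
  if (!identical(cube$variable_kind, clim$variable_kind))
    stop("cube holds '", cube$variable_kind, "' but climatology is for '",
         clim$variable_kind, "'")
  years <- cube_n_years(cube)
  if (is.null(event_type)) {
    event_type <- switch(cube$variable_kind,
      sst = "MHW", air_temp = "HW", precip = "precip",
      stop("event_type must be given for variable '", cube$variable_kind, "'"))
  }
  event_type <- match.arg(event_type, EVENT_TYPES)
  if (is.null(min_duration))
    min_duration <- if (event_type == "MHW") 5L else 3L
  g <- cube$grid
  npix <- g$nlat * g$nlon
  vals <- cube$values
  dim(vals) <- c(cube$nt, npix)
  thr <- clim$threshold
  dim(thr) <- c(DAYS_PER_YEAR, npix)
  ref <- if (intensity_ref == "seasonal_mean") clim$seasonal_mean else clim$threshold
  dim(ref) <- c(DAYS_PER_YEAR, npix)
  doy <- cube_doy(seq_len(cube$nt))
  if (is.null(pixel_mask)) {
    pixel_mask <- matrix(TRUE, g$nlat, g$nlon)
  } else {
    stopifnot(is.logical(pixel_mask), all(dim(pixel_mask) == c(g$nlat, g$nlon)))
  }
  has_data <- matrix(colSums(!is.na(vals)) > 0, g$nlat, g$nlon)
  valid <- pixel_mask & has_data
  res <- vector("list", npix)
  for (p in which(as.vector(valid))) {
    x <- vals[, p]
    exceed <- !is.na(x) & x > thr[doy, p]
    r <- rle(exceed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (join_gap > 0 && length(r$values) > 2) {
      # bridge short FALSE gaps flanked by exceedance runs
      gap <- which(!r$values & r$lengths <= join_gap)
      gap <- gap[gap > 1 & gap < length(r$values)]
      if (length(gap)) {
        exceed[unlist(mapply(seq, starts[gap], ends[gap], SIMPLIFY = FALSE))] <- TRUE
        r <- rle(exceed)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
      }
    }
    keep <- r$values & (if (min_rule == "geq") r$lengths >= min_duration
                        else r$lengths > min_duration)
    if (!any(keep)) next
    ev_start <- starts[keep]; ev_end <- ends[keep]
    inten <- mapply(function(s, e) {
      days <- s:e
      mean(x[days] - ref[doy[days], p])
    }, ev_start, ev_end)
    res[[p]] <- tibble::tibble(
      lat_idx = (p - 1L) %% g$nlat + 1L,
      lon_idx = (p - 1L) %/% g$nlat + 1L,
      start = ev_start, end = ev_end,
      duration = ev_end - ev_start + 1L,
      mean_intensity = as.numeric(inten))
  }
  events <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(events))
    events <- tibble::tibble(lat_idx = integer(), lon_idx = integer(),
                             start = integer(), end = integer(),
                             duration = integer(), mean_intensity = numeric())
  structure(list(events = events, event_type = event_type,
                 record_years = years, grid = g, pixels_valid = valid,
                 units = cube$units, min_duration = as.integer(min_duration)),
            class = "event_catalog")
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("<event_catalog> %s: %d events over %d yr on %dx%d grid\n",
              x$event_type, nrow(x$events), x$record_years,
              x$grid$nlat, x$grid$nlon))
  invisible(x)
}

#' Summarize an event catalog into metric layers
#'
#' Per pixel: `intensity` = mean of the events' mean intensities,
#' `duration` = mean event duration (days), `frequency` = total extreme
#' days in kept events divided by the record length (days/year). Pixels
#' searched but without events carry frequency 0 and missing intensity
#' and duration; pixels outside the search mask are missing everywhere.
#'
#' @param catalog An [detect_events()] catalog.
#' @return Named list of three `metric_layer` objects (`intensity`,
#'   `duration`, `frequency`).
#' @export
summarize_events <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  g <- catalog$grid
  base <- matrix(NA_real_, g$nlat, g$nlon)
  freq <- base
  freq[catalog$pixels_valid] <- 0
  inten <- base; dur <- base
  ev <- catalog$events
  if (nrow(ev)) {
    dt <- data.table::as.data.table(ev)
    agg <- dt[, list(intensity = mean(mean_intensity),
                     duration = mean(duration),
                     days = sum(duration)),
              by = list(lat_idx, lon_idx)]
    idx <- cbind(agg$lat_idx, agg$lon_idx)
    inten[idx] <- agg$intensity
    dur[idx] <- agg$duration
    freq[idx] <- agg$days / catalog$record_years
  }
  list(
    intensity = metric_layer(inten, catalog$event_type, "intensity",
                             catalog$units, g),
    duration = metric_layer(dur, catalog$event_type, "duration", "days", g),
    frequency = metric_layer(freq, catalog$event_type, "frequency",
                             "days/year", g)
  )
}
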