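#' Annual event-metric series
#'
#' Assigns every event to the year containing its start day (full
#' duration attributed there) and tallies, per pixel and year: the mean
#' event intensity, the mean event duration, and the number of extreme
#' event days (frequency). Years without events carry 0 frequency on
#' searched pixels and missing intensity/duration.
#'
#' @param catalog An [detect_events()] catalog.
#' @return An object of class `annual_series` with arrays
#'   `c(years, nlat, nlon)` per metric.
#' @export
annual_metrics <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  g <- catalog$grid
  ny <- catalog$record_years
  npix <- g$nlat * g$nlon
  freq <- array(NA_real_, c(ny, npix))
  freq[, as.vector(catalog$pixels_valid)] <- 0
  inten <- array(NA_real_, c(ny, npix))
  dur <- array(NA_real_, c(ny, npix))
  ev <- catalog$events
  if (nrow(ev)) {
    dt <- data.table::as.data.table(ev)
    dt[, year := (start - 1L) %/% DAYS_PER_YEAR + 1L]
    dt[, pix := lat_idx + (lon_idx - 1L) * g$nlat]
    agg <- dt[, list(intensity = mean(mean_intensity),
                     duration = mean(duration),
                     days = sum(duration)),
              by = list(pix, year)]
    idx <- cbind(agg$year, agg$pix)
    inten[idx] <- agg$intensity
    dur[idx] <- agg$duration
    freq[idx] <- agg$days
  }
  dim(freq) <- c(ny, g$nlat, g$nlon)
  dim(inten) <- c(ny, g$nlat, g$nlon)
  dim(dur) <- c(ny, g$nlat, g$nlon)
  structure(list(intensity = inten, duration = dur, frequency = freq,
                 years = ny, event_type = catalog$event_type,
                 units = catalog$units, grid = g),
            class = "annual_series")
}

#' Per-pixel least-squares trend of an annual metric
#'
#' Ordinary least squares of the annual metric on the (centred) year
#' index, with the two-sided t-test p-value for the slope. Pixels with
#' fewer than `min_years` non-missing years are left missing rather than
#' fitted. A perfectly constant series has slope 0 and p-value 1; an
#' exactly linear non-constant series has p-value 0.
#'
#' @param series An [annual_metrics()] object.
#' @param metric `"intensity"`, `"duration"` or `"frequency"`.
#' @param min_years Minimum non-missing years to fit (default 10).
#' @return An object of class `trend_layer` with matrices `slope`
#'   (metric units/year), `p_value` and `n_years`.
#' @export
ols_trend <- function(series, metric = c("frequency", "intensity", "duration"),
                      min_years = 10L) {
  stopifnot(inherits(series, "annual_series"))
  metric <- match.arg(metric)
  y_arr <- series[[metric]]
  g <- series$grid
  ny <- series$years
  dim(y_arr) <- c(ny, g$nlat * g$nlon)
  t_idx <- seq_len(ny) - (ny + 1) / 2  # centred year index
  slope <- p_val <- rep(NA_real_, ncol(y_arr))
  n_used <- integer(ncol(y_arr))
  for (p in seq_len(ncol(y_arr))) {
    y <- y_arr[, p]
    ok <- !is.na(y)
    n <- sum(ok)
    n_used[p] <- n
    if (n < max(min_years, 3L)) next
    x <- t_idx[ok]; yy <- y[ok]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) next
    b <- sum(xc * yy) / sxx
    res <- yy - mean(yy) - b * xc
    rss <- sum(res^2)
    slope[p] <- b
    if (rss <= 0) {
      p_val[p] <- if (b == 0) 1 else 0
    } else {
      se <- sqrt(rss / (n - 2) / sxx)
      p_val[p] <- 2 * pt(-abs(b / se), df = n - 2)
    }
  }
  structure(list(
    slope = matrix(slope, g$nlat, g$nlon),
    p_value = matrix(p_val, g$nlat, g$nlon),
    n_years = matrix(n_used, g$nlat, g$nlon),
    event_type = series$event_type, metric = metric,
    units = paste0(metric_units(metric, series$units), "/year"),
    grid = g, filtered = FALSE, alpha = NA_real_
  ), class = "trend_layer")
}

metric_units <- function(metric, field_units) {
  switch(metric, intensity = field_units, duration = "days",
         frequency = "days")
}

#' @export
print.trend_layer <- function(x, ...) {
  cat(sprintf("<trend_layer> %s %s [%s]%s: %d fitted pixels\n",
              x$event_type, x$metric, x$units,
              if (x$filtered) sprintf(" (filtered, alpha=%g)", x$alpha) else "",
              sum(!is.na(x$slope))))
  invisible(x)
}

#' Keep only positive and significant trends
#'
#' Retains a pixel when its slope is strictly positive and its two-sided
#' p-value is below `alpha`; all other pixels become missing. Only such
#' pixels enter cumulative trend maps, since increasing extremes are the
#' trends expected to harm the resident species.
#'
#' @param trend A [ols_trend()] layer.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The filtered `trend_layer`, with a logical `retained` matrix.
#' @export
filter_positive_significant <- function(trend, alpha = 0.05) {
  stopifnot(inherits(trend, "trend_layer"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  keep <- !is.na(trend$slope) & !is.na(trend$p_value) &
    trend$slope > 0 & trend$p_value < alpha
  out <- trend
  out$slope[!keep] <- NA_real_
  out$p_value[!keep] <- NA_real_
  out$retained <- keep
  out$filtered <- TRUE
  out$alpha <- alpha
  out
}

#' Cumulative trend layer with combination attribution
#'
#' Follows the same workflow as the cumulative mean, applied to filtered
#' trend slopes: each layer's retained slopes are min-max normalized over
#' its retained pixels (non-retained pixels contribute 0), the layers are
#' summed and the total re-normalized to `[0, 1]`. Attribution is the
#' *set* of event types retained at each pixel (a combination map), not a
#' single dominant type.
#'
#' @param layers List of [filter_positive_significant()] trend layers of
#'   one environment and metric.
#' @param environment `"sea"` or `"land"`.
#' @param renorm `"minmax"` (default) or `"sum"` (see [cumulative_mean()]).
#' @return A `cumulative_layer` with `values`, `combination` (character
#'   matrix, types joined by `+`, `""` where none) and `n_types`.
#' @export
cumulative_trend <- function(layers, environment = c("sea", "land"),
                             renorm = c("minmax", "sum")) {
  environment <- match.arg(environment)
  renorm <- match.arg(renorm)
  if (!length(layers)) stop("no layers supplied")
  if (!all(vapply(layers, inherits, TRUE, "trend_layer")))
    stop("all inputs must be trend_layer objects")
  if (!all(vapply(layers, function(l) isTRUE(l$filtered), TRUE)))
    stop("layers must pass through filter_positive_significant() first")
  metric <- unique(vapply(layers, function(l) l$metric, ""))
  if (length(metric) != 1) stop("layers mix metrics")
  g <- layers[[1]]$grid
  if (!all(vapply(layers, function(l) grids_identical(l$grid, g), TRUE)))
    stop("layers are on different grids")
  allowed <- event_types(environment)
  types <- vapply(layers, function(l) l$event_type, "")
  bad <- setdiff(types, allowed)
  if (length(bad))
    stop("event type(s) ", paste(bad, collapse = ", "),
         " do not belong to the ", environment, " environment")
  layers <- layers[order(match(types, allowed))]
  types <- vapply(layers, function(l) l$event_type, "")

  domain <- surface_mask(g, environment)
  npix <- g$nlat * g$nlon
  total <- rep(0, npix)
  retained_mat <- matrix(FALSE, npix, length(layers))
  for (k in seq_along(layers)) {
    l <- layers[[k]]
    ret <- as.vector(l$retained)
    retained_mat[, k] <- ret
    if (!any(ret)) next
    s <- as.vector(l$slope)[ret]
    lo <- min(s); hi <- max(s)
    contrib <- rep(0, npix)
    if (hi == lo) {
      warning("degenerate normalization for ", l$event_type,
              " trend layer (single retained value): contributes zeros")
    } else {
      contrib[ret] <- (s - lo) / (hi - lo)
    }
    total <- total + contrib
  }
  total[!as.vector(domain)] <- NA_real_
  any_ret <- rowSums(retained_mat) > 0
  if (any(any_ret & !is.na(total)))
    total <- renorm_values(total, renorm)
  combo <- vapply(seq_len(npix), function(p) {
    if (!domain[p]) return(NA_character_)
    paste(types[retained_mat[p, ]], collapse = "+")
  }, "")
  structure(list(
    values = matrix(total, g$nlat, g$nlon),
    combination = matrix(combo, g$nlat, g$nlon),
    n_types = matrix(rowSums(retained_mat), g$nlat, g$nlon),
    environment = environment, metric = metric, types = types,
    grid = g, flavour = "trend"
  ), class = "cumulative_layer")
}

#' Area fractions of positive-and-significant trends
#'
#' Counts, per environment and metric, the share of environment-role
#' cells (mixed coastal cells count in both environments) retaining at
#' least one event type's positive and significant trend, the share
#' retaining a single type, the share with multi-type overlap, and the
#' breakdown by each specific combination.
#'
#' @param layers List of filtered [ols_trend()] layers (one environment,
#'   one metric).
#' @param environment `"sea"` or `"land"`.
#' @return A [tibble::tibble] with columns `environment`, `metric`,
#'   `combination` (specific combinations plus the summary rows `any`,
#'   `single` and `multiple`), `n_cells` and `pct` (of the environment
#'   area).
#' @export
trend_area_fractions <- function(layers, environment = c("sea", "land")) {
  environment <- match.arg(environment)
  if (!all(vapply(layers, function(l) isTRUE(l$filtered), TRUE)))
    stop("layers must pass through filter_positive_significant() first")
  g <- layers[[1]]$grid
  allowed <- event_types(environment)
  types <- vapply(layers, function(l) l$event_type, "")
  layers <- layers[order(match(types, allowed))]
  types <- vapply(layers, function(l) l$event_type, "")
  domain <- as.vector(surface_mask(g, environment))
  n_env <- sum(domain)
  ret <- vapply(layers, function(l) as.vector(l$retained) & domain,
                logical(length(domain)))
  ret <- matrix(ret, ncol = length(layers))
  n_types_pix <- rowSums(ret)
  combo <- apply(ret, 1, function(r) paste(types[r], collapse = "+"))
  combo_tab <- table(combo[n_types_pix > 0])
  metric <- layers[[1]]$metric
  rows <- tibble::tibble(
    environment = environment, metric = metric,
    combination = c(names(combo_tab), "any", "single", "multiple"),
    n_cells = c(as.integer(combo_tab), sum(n_types_pix > 0),
                sum(n_types_pix == 1), sum(n_types_pix > 1))
  )
  rows$pct <- 100 * rows$n_cells / n_env
  rows
}
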