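#' Per-pixel metric layer
#'
#' A scalar field for one event type and one metric (`intensity`,
#' `duration` or `frequency`).
#'
#' @param values Numeric `nlat x nlon` matrix (NA = missing).
#' @param event_type One of the five event types.
#' @param metric `"intensity"`, `"duration"` or `"frequency"`.
#' @param units Units label.
#' @param grid A [grid_def()].
#' @param normalized Whether the layer is a dimensionless min-max
#'   normalized field.
#' @return An object of class `metric_layer`.
#' @export
metric_layer <- function(values, event_type, metric, units, grid,
                         normalized = FALSE) {
  assert_grid_def(grid)
  event_type <- match.arg(event_type, EVENT_TYPES)
  metric <- match.arg(metric, c("intensity", "duration", "frequency"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nlat, grid$nlon)))
    stop("layer dimensions do not match the grid")
  structure(list(values = values, event_type = event_type, metric = metric,
                 units = units, grid = grid, normalized = isTRUE(normalized)),
            class = "metric_layer")
}

#' @export
print.metric_layer <- function(x, ...) {
  cat(sprintf("<metric_layer> %s %s [%s]%s, %d/%d pixels non-missing\n",
              x$event_type, x$metric, x$units,
              if (x$normalized) " (normalized)" else "",
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

#' Min-max normalization of a metric layer
#'
#' Rescales `x' = (x - xmin) / (xmax - xmin)` over the non-missing pixels
#' inside `mask`, so the smallest value maps to 0 and the largest to 1.
#' The result is invariant to positive affine transforms of the input.
#' A layer with no spread (`xmax == xmin`) maps to all zeros with a
#' warning, since the normalization then carries no information.
#'
#' @param layer A [metric_layer()].
#' @param mask Optional logical `nlat x nlon` domain mask (e.g. a
#'   [surface_mask()]); pixels outside become missing.
#' @return A dimensionless [metric_layer()] with values in `[0, 1]`.
#' @export
minmax_normalize <- function(layer, mask = NULL) {
  stopifnot(inherits(layer, "metric_layer"))
  vals <- layer$values
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(vals)))
    vals[!mask] <- NA_real_
  }
  ok <- !is.na(vals)
  if (!any(ok)) stop("cannot normalize: layer has no non-missing pixel in mask")
  lo <- min(vals[ok]); hi <- max(vals[ok])
  if (hi == lo) {
    warning("degenerate normalization (xmax == xmin): layer mapped to all zeros")
    vals[ok] <- 0
  } else {
    vals <- (vals - lo) / (hi - lo)
  }
  metric_layer(vals, layer$event_type, layer$metric, "1", layer$grid,
               normalized = TRUE)
}

check_stack <- function(layers, environment) {
  if (!length(layers)) stop("no layers supplied")
  if (!all(vapply(layers, inherits, TRUE, "metric_layer")))
    stop("all inputs must be metric_layer objects")
  metric <- unique(vapply(layers, function(l) l$metric, ""))
  if (length(metric) != 1) stop("layers mix metrics: ",
                                paste(metric, collapse = ", "))
  g <- layers[[1]]$grid
  if (!all(vapply(layers, function(l) grids_identical(l$grid, g), TRUE)))
    stop("layers are on different grids")
  types <- vapply(layers, function(l) l$event_type, "")
  if (anyDuplicated(types)) stop("duplicate event types in stack")
  allowed <- event_types(environment)
  bad <- setdiff(types, allowed)
  if (length(bad))
    stop("event type(s) ", paste(bad, collapse = ", "),
         " do not belong to the ", environment, " environment")
  if (!all(vapply(layers, function(l) l$normalized, TRUE)))
    stop("layers must be min-max normalized before stacking")
  # order by canonical type order so tie-breaks are deterministic
  layers[order(match(types, allowed))]
}

#' Cumulative mean layer: normalized, equally weighted stack
#'
#' Sums the normalized metric layers of all event types of one
#' environment (sea: MHW + extreme wind at sea; land: HW + extreme wind
#' on land + extreme precipitation) pixel by pixel, then re-normalizes
#' the sum to `[0, 1]` with the same min-max formula. Pixels missing in
#' every input are missing in the output; pixels present in at least one
#' input treat the others as contributing 0. The per-pixel dominant event
#' type is attached.
#'
#' @param layers List of normalized [metric_layer()]s (one per event
#'   type, same metric).
#' @param environment `"sea"` or `"land"`.
#' @param renorm `"minmax"` (default) re-normalizes the stacked field to
#'   `[0, 1]`; `"sum"` instead divides by the field total so the map sums
#'   to one.
#' @return An object of class `cumulative_layer` with `values`,
#'   `dominant` (character matrix) and the contributing `types`.
#' @export
cumulative_mean <- function(layers, environment = c("sea", "land"),
                            renorm = c("minmax", "sum")) {
  environment <- match.arg(environment)
  renorm <- match.arg(renorm)
  layers <- check_stack(layers, environment)
  g <- layers[[1]]$grid
  stack <- vapply(layers, function(l) l$values, layers[[1]]$values)
  dim(stack) <- c(g$nlat * g$nlon, length(layers))
  n_ok <- rowSums(!is.na(stack))
  total <- rowSums(stack, na.rm = TRUE)
  total[n_ok == 0] <- NA_real_
  total <- renorm_values(total, renorm)
  vals <- matrix(total, g$nlat, g$nlon)
  structure(list(
    values = vals, dominant = dominant_event(layers),
    environment = environment, metric = layers[[1]]$metric,
    types = vapply(layers, function(l) l$event_type, ""),
    grid = g, flavour = "mean"
  ), class = "cumulative_layer")
}

renorm_values <- function(x, renorm) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  if (renorm == "sum") {
    s <- sum(x[ok])
    if (s == 0) {
      warning("degenerate sum renormalization (total 0): values left at 0")
      return(x)
    }
    return(x / s)
  }
  lo <- min(x[ok]); hi <- max(x[ok])
  if (hi == lo) {
    warning("degenerate normalization (xmax == xmin): layer mapped to all zeros")
    x[ok] <- 0
    return(x)
  }
  (x - lo) / (hi - lo)
}

#' @export
print.cumulative_layer <- function(x, ...) {
  cat(sprintf("<cumulative_layer> %s %s (%s): types %s\n",
              x$environment, x$metric, x$flavour,
              paste(x$types, collapse = "+")))
  invisible(x)
}

#' Dominant event type per pixel
#'
#' The event type whose normalized layer value is largest at each pixel.
#' Exact ties go to the first type in canonical order (`MHW`, `wind_sea`
#' at sea; `HW`, `wind_land`, `precip` on land). Pixels missing in every
#' layer are `NA`.
#'
#' @param layers List of normalized [metric_layer()]s of one environment.
#' @param environment `"sea"`, `"land"`, or `NULL` to infer it from the
#'   layer types.
#' @return Character `nlat x nlon` matrix of event types.
#' @export
dominant_event <- function(layers, environment = NULL) {
  if (is.null(environment)) {
    types <- vapply(layers, function(l) l$event_type, "")
    environment <- if (all(types %in% EVENT_TYPES_SEA)) "sea" else "land"
  }
  layers <- check_stack(layers, environment)
  g <- layers[[1]]$grid
  types <- vapply(layers, function(l) l$event_type, "")
  stack <- vapply(layers, function(l) l$values, layers[[1]]$values)
  dim(stack) <- c(g$nlat * g$nlon, length(layers))
  out <- rep(NA_character_, nrow(stack))
  any_ok <- rowSums(!is.na(stack)) > 0
  if (any(any_ok)) {
    s <- stack[any_ok, , drop = FALSE]
    s[is.na(s)] <- -Inf
    out[any_ok] <- types[max.col(s, ties.method = "first")]
  }
  matrix(out, g$nlat, g$nlon)
}

#' Classify a normalized value into quartile exposure classes
#'
#' Bins `[0, 0.25)` low, `[0.25, 0.5)` medium, `[0.5, 0.75)` high and
#' `[0.75, 1]` very high (left-closed bins, top bin closed).
#'
#' @param x Numeric vector (or matrix) of values in `[0, 1]`; NA passes
#'   through.
#' @return Ordered factor with levels `low < medium < high < very high`
#'   (a matrix input returns a character matrix).
#' @export
classify_quartile <- function(x) {
  v <- as.vector(x)
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad)) stop("values outside [0, 1] cannot be classified")
  lev <- c("low", "medium", "high", "very high")
  cls <- lev[findInterval(v, c(0.25, 0.5, 0.75)) + 1L]
  if (is.matrix(x)) return(matrix(cls, nrow(x), ncol(x)))
  factor(cls, levels = lev, ordered = TRUE)
}
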