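#' Pipeline configuration
#'
#' Collects everything a full run needs: the grid, the record length, the
#' detection settings, the trend filter level, the hotspot source and the
#' seed. The configuration round-trips losslessly through its YAML file
#' form ([write_pipeline_config()] / [read_pipeline_config()]), and a run
#' is a pure function of configuration + seed.
#'
#' @param grid A [grid_def()] (with surface classes).
#' @param years Record length in 365-day years (default 31).
#' @param n_species Number of synthetic hotspot species (ignored when
#'   `hotspot_path` is given).
#' @param hotspot_path Optional GeoJSON file of real hotspot polygons.
#' @param episodes Optional data frame of episodes to inject, with an
#'   extra `variable_kind` column naming the target cube.
#' @param percentile Climatology percentile (default 90).
#' @param window_days,smooth_days Climatology windows (defaults 11, 31).
#' @param min_duration_marine,min_duration_atmos Minimum event durations
#'   in days (defaults 5 and 3).
#' @param alpha Trend significance level (default 0.05).
#' @param min_trend_years Minimum years for intensity/duration trend fits
#'   (default 10).
#' @param renorm `"minmax"` or `"sum"` re-normalization of stacked layers.
#' @param raster_rule Hotspot cell membership rule (`"intersect"` or
#'   `"centre"`).
#' @param level_trends Named numeric vector of level trends (units/year)
#'   per variable kind, e.g. `c(sst = 0.02)`; unnamed kinds get 0.
#' @param outdir Output directory for the product bundle.
#' @param seed Integer master seed; per-variable seeds are derived from
#'   it by fixed small offsets.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid, years = 31L, n_species = 4L,
                            hotspot_path = NULL, episodes = NULL,
                            percentile = 90, window_days = 11L,
                            smooth_days = 31L, min_duration_marine = 5L,
                            min_duration_atmos = 3L, alpha = 0.05,
                            min_trend_years = 10L,
                            renorm = c("minmax", "sum"),
                            raster_rule = c("intersect", "centre"),
                            level_trends = NULL,
                            outdir = "cumulex_out", seed = 1L) {
  assert_grid_def(grid)
  renorm <- match.arg(renorm)
  raster_rule <- match.arg(raster_rule)
  structure(list(
    grid = grid, years = as.integer(years), n_species = as.integer(n_species),
    hotspot_path = hotspot_path, episodes = episodes,
    percentile = percentile, window_days = as.integer(window_days),
    smooth_days = as.integer(smooth_days),
    min_duration_marine = as.integer(min_duration_marine),
    min_duration_atmos = as.integer(min_duration_atmos),
    alpha = alpha, min_trend_years = as.integer(min_trend_years),
    renorm = renorm, raster_rule = raster_rule,
    level_trends = level_trends, outdir = outdir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  g <- config$grid
  lst <- unclass(config)
  lst$grid <- list(lat_min = min(g$lat_edges), lat_max = max(g$lat_edges),
                   lon_min = min(g$lon_edges), lon_max = max(g$lon_edges),
                   cell_size = g$cell_size,
                   surface = as.vector(g$surface))
  if (!is.null(lst$episodes)) lst$episodes <- as.list(as.data.frame(lst$episodes))
  if (!is.null(lst$level_trends)) lst$level_trends <- as.list(lst$level_trends)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  gl <- lst$grid
  nlat <- as.integer(round((gl$lat_max - gl$lat_min) / gl$cell_size))
  nlon <- as.integer(round((gl$lon_max - gl$lon_min) / gl$cell_size))
  grid <- grid_def(gl$lat_min, gl$lat_max, gl$lon_min, gl$lon_max,
                   cell_size = gl$cell_size,
                   surface = matrix(gl$surface, nlat, nlon))
  episodes <- if (!is.null(lst$episodes)) tibble::as_tibble(lst$episodes)
  lt <- if (!is.null(lst$level_trends)) unlist(lst$level_trends)
  pipeline_config(
    grid = grid, years = lst$years, n_species = lst$n_species,
    hotspot_path = lst$hotspot_path, episodes = episodes,
    percentile = lst$percentile, window_days = lst$window_days,
    smooth_days = lst$smooth_days,
    min_duration_marine = lst$min_duration_marine,
    min_duration_atmos = lst$min_duration_atmos, alpha = lst$alpha,
    min_trend_years = lst$min_trend_years, renorm = lst$renorm,
    raster_rule = lst$raster_rule, level_trends = lt,
    outdir = lst$outdir, seed = lst$seed)
}

# polynomial rolling hash over the YAML form: deterministic provenance id
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  bytes <- as.integer(charToRaw(paste(readLines(tmp), collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full cumulative extreme-events pipeline
#'
#' Executes the whole chain on synthetic inputs: simulate the five daily
#' variables (SST, air temperature, wind u/v, precipitation) and derive
#' wind speed; build each variable's percentile climatology and detect
#' the five event types (MHW and extreme wind at sea on sea-role pixels;
#' HW, extreme wind on land and extreme precipitation on land-role
#' pixels); summarize events into intensity/duration/frequency layers;
#' stack normalized layers into cumulative-mean maps with dominant-type
#' attribution; fit per-pixel annual trends, filter positive and
#' significant slopes, stack them into cumulative-trend maps with
#' combination attribution and area-fraction accounting; rasterize the
#' hotspots and build the species mean- and trend-exposure tables. All
#' products are written to `config$outdir` as CSV (plus the hotspots as
#' GeoJSON and a JSON run manifest) and returned invisibly.
#'
#' Re-running with an identical configuration (including the seed)
#' reproduces every product byte for byte.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the catalogs, layers, cumulative maps,
#'   trend products, exposure tables and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[cumulex] ", ...)
  g <- config$grid
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    lt <- function(kind) {
      if (!is.null(config$level_trends) && kind %in% names(config$level_trends))
        config$level_trends[[kind]] else 0
    }
    say("simulating daily fields (", config$years, " years)")
    kinds <- c("sst", "air_temp", "wind_u", "wind_v", "precip")
    cubes <- list()
    for (k in seq_along(kinds)) {
      kind <- kinds[k]
      spec <- field_spec(kind, g, years = config$years,
                         level_trend = lt(kind), seed = config$seed + k)
      cubes[[kind]] <- generate_daily_cube(spec)
      if (!is.null(config$episodes)) {
        eps <- config$episodes[config$episodes$variable_kind == kind, ]
        if (nrow(eps)) cubes[[kind]] <- inject_episodes(cubes[[kind]], eps)
      }
    }
    cubes$wind <- wind_speed(cubes$wind_u, cubes$wind_v)

    stage <- "detect"
    sea <- surface_mask(g, "sea"); land <- surface_mask(g, "land")
    setup <- list(
      MHW = list(cube = "sst", mask = sea, min = config$min_duration_marine),
      wind_sea = list(cube = "wind", mask = sea, min = config$min_duration_atmos),
      HW = list(cube = "air_temp", mask = land, min = config$min_duration_atmos),
      wind_land = list(cube = "wind", mask = land, min = config$min_duration_atmos),
      precip = list(cube = "precip", mask = land, min = config$min_duration_atmos))
    catalogs <- list()
    clims <- list()
    for (type in names(setup)) {
      s <- setup[[type]]
      say("detecting ", type, " events")
      if (is.null(clims[[s$cube]]))
        clims[[s$cube]] <- daily_climatology(
          cubes[[s$cube]], config$window_days, config$smooth_days,
          config$percentile)
      catalogs[[type]] <- detect_events(
        cubes[[s$cube]], clims[[s$cube]], event_type = type,
        min_duration = s$min, pixel_mask = s$mask)
    }

    stage <- "summarize"
    layers <- lapply(catalogs, summarize_events)
    metrics <- c("intensity", "duration", "frequency")
    envs <- c(sea = "sea", land = "land")

    stage <- "cumulate"
    cmean <- list()
    for (env in envs) {
      msk <- surface_mask(g, env)
      for (met in metrics) {
        say("cumulative mean: ", env, " ", met)
        norm <- lapply(event_types(env), function(tp)
          minmax_normalize(layers[[tp]][[met]], mask = msk))
        cmean[[paste(env, met, sep = "_")]] <-
          cumulative_mean(norm, env, renorm = config$renorm)
      }
    }

    stage <- "trend"
    annual <- lapply(catalogs, annual_metrics)
    filtered <- list()
    ctrend <- list()
    fractions <- list()
    for (env in envs) {
      for (met in metrics) {
        say("cumulative trend: ", env, " ", met)
        fl <- lapply(event_types(env), function(tp)
          filter_positive_significant(
            ols_trend(annual[[tp]], met, config$min_trend_years),
            config$alpha))
        names(fl) <- event_types(env)
        filtered[[paste(env, met, sep = "_")]] <- fl
        ctrend[[paste(env, met, sep = "_")]] <-
          cumulative_trend(fl, env, renorm = config$renorm)
        fractions[[paste(env, met, sep = "_")]] <-
          trend_area_fractions(fl, env)
      }
    }
    area_fractions <- do.call(rbind, fractions)

    stage <- "exposure"
    hotspots <- if (!is.null(config$hotspot_path)) {
      say("reading hotspots from ", config$hotspot_path)
      read_hotspots_geojson(config$hotspot_path)
    } else {
      say("generating ", config$n_species, " synthetic hotspots")
      generate_hotspots(g, config$n_species, seed = config$seed + 10L)
    }
    masks <- rasterize_hotspots(hotspots, g, rule = config$raster_rule)
    mean_tables <- list(); trend_tables <- list()
    for (env in envs) {
      for (met in metrics) {
        key <- paste(env, met, sep = "_")
        raw <- lapply(event_types(env), function(tp) layers[[tp]][[met]])
        mean_tables[[key]] <- normalize_species(
          suppressMessages(species_mean_exposure(raw, masks, env)))
        trend_tables[[key]] <- normalize_species(
          suppressMessages(species_trend_exposure(filtered[[key]], masks, env)))
      }
    }

    stage <- "write"
    say("writing product bundle to ", config$outdir)
    out <- function(...) file.path(config$outdir, ...)
    for (type in names(catalogs))
      data.table::fwrite(catalogs[[type]]$events, out(paste0("events_", type, ".csv")))
    lat <- rep(g$lat_centers, times = g$nlon)
    lon <- rep(g$lon_centers, each = g$nlat)
    for (key in names(cmean)) {
      cl <- cmean[[key]]
      data.table::fwrite(data.table::data.table(
        lat = lat, lon = lon, value = as.vector(cl$values),
        dominant = as.vector(cl$dominant),
        class = as.vector(ifelse(is.na(cl$values), NA_character_,
                                 as.character(classify_quartile(cl$values))))),
        out(paste0("cumulative_mean_", key, ".csv")))
      tl <- ctrend[[key]]
      data.table::fwrite(data.table::data.table(
        lat = lat, lon = lon, value = as.vector(tl$values),
        combination = as.vector(tl$combination),
        n_types = as.vector(tl$n_types)),
        out(paste0("cumulative_trend_", key, ".csv")))
      data.table::fwrite(mean_tables[[key]], out(paste0("species_mean_", key, ".csv")))
      data.table::fwrite(trend_tables[[key]], out(paste0("species_trend_", key, ".csv")))
    }
    data.table::fwrite(area_fractions, out("area_fractions.csv"))
    write_hotspots_geojson(hotspots, out("hotspots.geojson"))
    manifest <- list(
      package = "cumulex",
      version = as.character(utils::packageVersion("cumulex")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed, config_hash = config_hash(config),
      grid = sprintf("%dx%d @ %g deg", g$nlat, g$nlon, g$cell_size),
      years = config$years,
      n_events = vapply(catalogs, function(ct) nrow(ct$events), 0L))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               out("manifest.json"))
    list(config = config, catalogs = catalogs, layers = layers,
         cumulative_mean = cmean, annual = annual, filtered = filtered,
         cumulative_trend = ctrend, area_fractions = area_fractions,
         hotspots = hotspots, masks = masks, mean_tables = mean_tables,
         trend_tables = trend_tables, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
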