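#' Read case points from CSV or GeoJSON
#'
#' CSV needs `x`, `y` columns and optionally `label`, `partition`;
#' GeoJSON must be a FeatureCollection of Point features (properties may
#' carry `label`/`partition`). Malformed rows are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @param format `"csv"` or `"geojson"`; default guessed from the
#'   extension.
#' @return A [case_points()] set.
#' @export
read_points <- function(path, format = NULL) {
  if (!file.exists(path)) stop_spatrisk("io", "no such file: %s", path)
  if (is.null(format))
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE))
      "geojson" else "csv"
  format <- match.arg(format, c("csv", "geojson"))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop_spatrisk("io", "empty input file: %s", path)
    if (!all(c("x", "y") %in% names(df)))
      stop_spatrisk("schema", "CSV %s lacks coordinate columns x, y", path)
    x <- suppressWarnings(as.numeric(df$x))
    y <- suppressWarnings(as.numeric(df$y))
    bad <- which(!is.finite(x) | !is.finite(y))
    if (length(bad))
      stop_spatrisk("schema", "non-numeric coordinates at data line(s): %s",
                    paste(utils::head(bad, 10), collapse = ", "))
    case_points(x, y,
                label = if ("label" %in% names(df)) df$label else 1,
                partition = if ("partition" %in% names(df)) df$partition
                            else NA_character_)
  } else {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (is.null(feats) || !length(feats))
      stop_spatrisk("io", "empty or non-FeatureCollection GeoJSON: %s", path)
    coords <- t(vapply(feats, function(f) {
      if (!identical(f$geometry$type, "Point"))
        stop_spatrisk("schema", "non-Point geometry in %s", path)
      as.numeric(unlist(f$geometry$coordinates)[1:2])
    }, numeric(2)))
    getp <- function(key, default) vapply(feats, function(f)
      f$properties[[key]] %||% default, default)
    case_points(coords[, 1], coords[, 2],
                label = as.integer(getp("label", 1L)),
                partition = as.character(getp("partition", NA_character_)))
  }
}

#' Write case points to CSV or GeoJSON
#'
#' @param points a [case_points()] set.
#' @param path output path.
#' @param format `"csv"` or `"geojson"`; default guessed from extension.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE))
      "geojson" else "csv"
  format <- match.arg(format, c("csv", "geojson"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(points)), function(i) {
      props <- list(label = points$label[i])
      if (!is.na(points$partition[i])) props$partition <- points$partition[i]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(points$x[i], points$y[i])),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write rasters as ESRI ASCII grids
#'
#' The plain-text `.asc` grid format carries the full georeference
#' (lower-left corner, cell size, nodata value) and round-trips the cell
#' values exactly at the printed precision (17 significant digits, i.e.
#' lossless for doubles).
#'
#' @param raster a [criterion_raster()].
#' @param path file path.
#' @param nodata nodata sentinel written to file.
#' @return `write_raster_asc`: `path`, invisibly. `read_raster_asc`: a
#'   [criterion_raster()].
#' @export
write_raster_asc <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "criterion_raster"))
  a <- raster$area
  hdr <- c(sprintf("ncols %d", a$ncol),
           sprintf("nrows %d", a$nrow),
           sprintf("xllcorner %.10f", a$xmin),
           sprintf("yllcorner %.10f", a$ymin),
           sprintf("cellsize %.10f", a$cell),
           sprintf("NODATA_value %g", nodata))
  v <- raster$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_raster_asc
#' @param name variable name for the raster read back.
#' @param mask optional logical mask to reimpose (default: nodata cells).
#' @export
read_raster_asc <- function(path, name = NULL, mask = NULL) {
  if (!file.exists(path)) stop_spatrisk("io", "no such file: %s", path)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    row <- grep(paste0("^", key, "\\b"), hdr, ignore.case = TRUE, value = TRUE)
    if (!length(row)) stop_spatrisk("io", "missing header '%s' in %s", key, path)
    as.numeric(strsplit(trimws(row), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                 nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  if (is.null(mask)) mask <- !is.na(vals)
  if (!any(mask)) mask <- matrix(TRUE, nr, nc)
  area <- study_area(width = nc * cs, height = nr * cs, cell = cs,
                     xmin = xll, ymin = yll, mask = mask)
  criterion_raster(area, vals,
                   name = name %||% sub("\\.asc$", "", basename(path)))
}

#' Check that raster layers share one grid
#'
#' @param rasters named list of [criterion_raster()]s.
#' @return TRUE invisibly; misaligned layers raise an alignment error
#'   naming them.
#' @export
check_alignment <- function(rasters) {
  g0 <- rasters[[1]]$area
  bad <- names(rasters)[!vapply(rasters, function(r) same_grid(r$area, g0),
                                logical(1))]
  if (length(bad))
    stop_spatrisk("alignment", "layer(s) not on the common grid: %s",
                  paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. All randomness downstream
#' flows from `seed`; identical configs give bit-identical runs.
#'
#' @param seed master integer seed.
#' @param scenario a [synthetic_scenario()] (synthetic criteria source).
#' @param cell study-area grid resolution (map units).
#' @param criteria_source `"rasters"` (use the generated fields directly)
#'   or `"stations"` (sample stations per criterion and krige them back).
#' @param station_noise_sd measurement noise for `"stations"`.
#' @param binning_method,binning_k FR class binning.
#' @param weights_scheme,agg_cells Moran weights scheme and aggregation
#'   lattice size (units per axis).
#' @param train_fraction,split_rounding presence split.
#' @param absence_min_distance pseudo-absence exclusion radius (map units;
#'   NULL = 2 cells).
#' @param n_trees,mtry random-forest hyperparameters.
#' @param class_k risk classes on the final map.
#' @param out_dir output directory.
#' @return An object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(seed = 1L,
                            scenario = synthetic_scenario(seed = seed),
                            cell = 300,
                            criteria_source = c("rasters", "stations"),
                            station_noise_sd = 0.05,
                            binning_method = "natural_breaks",
                            binning_k = 5L,
                            weights_scheme = "queen",
                            agg_cells = 15L,
                            train_fraction = 0.7,
                            split_rounding = "round",
                            absence_min_distance = NULL,
                            n_trees = 100L,
                            mtry = NULL,
                            class_k = 5L,
                            out_dir = tempfile("spatrisk_run_")) {
  criteria_source <- match.arg(criteria_source)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_spatrisk("parameter", "train_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # hash the analytical config, not where it is written
  plain <- rapply(cfg, function(x)
    if (is.numeric(x)) signif(x, 12) else x, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full susceptibility pipeline
#'
#' Executes the stages in their methodological order — spatial database
#' (synthetic criteria, cases, split, pseudo-absences, optional kriging),
#' frequency-ratio weighting, spatial-autocorrelation screening,
#' random-forest modelling and mapping, validation and leave-one-out
#' sensitivity — writing every report and map under `config$out_dir` and
#' returning a manifest. A stage failure marks the manifest failed at that
#' stage and preserves the outputs already written.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @param stop_after optionally stop (successfully) after this stage:
#'   one of `"database"`, `"frequency_ratio"`, `"autocorrelation"`,
#'   `"random_forest"`, `"validation"`.
#' @return The run manifest (list), also written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE, stop_after = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(stop_after))
    stop_after <- match.arg(stop_after,
                            c("database", "frequency_ratio", "autocorrelation",
                              "random_forest", "validation"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("spatrisk")),
                   stages = list(), outputs = list(), status = "running")
  pth <- function(f) file.path(config$out_dir, f)
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(status = "ok",
                                      elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
    manifest$outputs[names(files)] <<- files
    if (identical(stop_after, stage))
      stop(structure(class = c("spatrisk_stage_done", "error", "condition"),
                     list(message = stage, call = NULL)))
  }
  env <- new.env()
  result <- tryCatch({
    stage <- "database"
    log_line("[%s] stage %s (seed %d, hash %s)", "spatrisk", stage,
             config$seed, manifest$config_hash)
    env$area <- default_study_area(cell = config$cell)
    env$criteria <- generate_criteria(env$area, config$scenario)
    check_alignment(env$criteria)
    if (config$criteria_source == "stations") {
      env$criteria <- lapply(seq_along(env$criteria), function(k) {
        r <- env$criteria[[k]]
        n_stn <- config$scenario$station_count[k]
        if (is.na(n_stn)) return(r)  # distance-style layers used directly
        stn <- sample_stations(r, n = n_stn, noise_sd = config$station_noise_sd,
                               seed = config$seed + 100L * k)
        fit <- fit_variogram_model(empirical_semivariogram(stn))
        ordinary_kriging(stn, fit, env$area)$prediction
      })
      names(env$criteria) <- config$scenario$criterion_names
    }
    env$cases <- generate_cases(env$area, env$criteria, config$scenario)
    env$cases <- split_points(env$cases, config$train_fraction,
                              seed = config$seed + 11L,
                              rounding = config$split_rounding)
    env$absences <- sample_pseudo_absence(env$cases, env$area,
                                          min_distance = config$absence_min_distance,
                                          seed = config$seed + 13L)
    env$absences <- split_points(env$absences, config$train_fraction,
                                 seed = config$seed + 17L,
                                 rounding = config$split_rounding)
    env$points <- rbind(env$cases, env$absences)
    write_points(env$cases, pth("cases.csv"))
    write_points(env$points, pth("points.geojson"))
    for (nm in names(env$criteria))
      write_raster_asc(env$criteria[[nm]], pth(sprintf("criterion_%s.asc", nm)))
    vg <- lapply(names(env$criteria), function(nm) {
      s <- sample_stations(env$criteria[[nm]],
                           n = min(200L, sum(!is.na(env$criteria[[nm]]$values))),
                           noise_sd = 0, seed = config$seed + 23L)
      attr(s, "variable_name") <- nm
      s
    })
    names(vg) <- names(env$criteria)
    env$variograms <- variogram_report(vg)
    jsonlite::write_json(env$variograms, pth("variogram_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    record(stage, list(cases = pth("cases.csv"), points = pth("points.geojson"),
                       variogram_report = pth("variogram_report.json")))

    stage <- "frequency_ratio"
    log_line("[%s] stage %s", "spatrisk", stage)
    env$fr <- fr_pipeline(env$cases, env$criteria,
                          method = config$binning_method, k = config$binning_k)
    frtab <- do.call(rbind, lapply(names(env$fr$tables), function(nm) {
      t <- as.data.frame(env$fr$tables[[nm]])
      cbind(criterion = nm, t)
    }))
    utils::write.csv(frtab, pth("fr_tables.csv"), row.names = FALSE)
    record(stage, list(fr_tables = pth("fr_tables.csv")))

    stage <- "autocorrelation"
    log_line("[%s] stage %s", "spatrisk", stage)
    env$units <- aggregate_points(env$cases, env$area,
                                  cell = (env$area$xmax - env$area$xmin) / config$agg_cells)
    W_m <- build_weights(env$units, scheme = config$weights_scheme,
                         row_standardize = TRUE)
    W_g <- build_weights(env$units, scheme = "distance_band",
                         row_standardize = FALSE)
    env$autocorr <- autocorr_report(env$units, W_m, W_g, seed = config$seed + 29L)
    jsonlite::write_json(env$autocorr, pth("autocorr_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    record(stage, list(autocorr_report = pth("autocorr_report.json")))

    stage <- "random_forest"
    log_line("[%s] stage %s", "spatrisk", stage)
    env$features <- extract_features(env$points, env$fr$surfaces)
    env$model <- train_random_forest(env$features, n_trees = config$n_trees,
                                     mtry = config$mtry,
                                     seed = config$seed + 31L)
    utils::write.csv(data.frame(criterion = names(env$model$importance),
                                importance = as.numeric(env$model$importance)),
                     pth("importance.csv"), row.names = FALSE)
    env$prob <- predict_susceptibility(env$model, env$fr$surfaces)
    env$classed <- classify_map(env$prob, k = config$class_k)
    write_raster_asc(env$prob, pth("susceptibility_prob.asc"))
    write_raster_asc(env$classed$classes, pth("susceptibility_class.asc"))
    record(stage, list(importance = pth("importance.csv"),
                       probability = pth("susceptibility_prob.asc"),
                       classes = pth("susceptibility_class.asc")))

    stage <- "validation"
    log_line("[%s] stage %s", "spatrisk", stage)
    env$validation <- validation_report(env$model, env$features)
    env$sensitivity <- run_sensitivity(env$features, n_trees = config$n_trees,
                                       mtry = config$mtry,
                                       seed = config$seed + 31L)
    jsonlite::write_json(env$validation, pth("validation_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(cbind(as.data.frame(env$sensitivity),
                           auc_all = attr(env$sensitivity, "auc_all")),
                     pth("sensitivity.csv"), row.names = FALSE)
    record(stage, list(validation_report = pth("validation_report.json"),
                       sensitivity = pth("sensitivity.csv")))
    manifest$status <- "ok"
    TRUE
  }, spatrisk_stage_done = function(e) {
    manifest$status <<- "ok"
    manifest$stopped_after <<- conditionMessage(e)
    TRUE
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    FALSE
  })
  manifest$elapsed_s <- as.numeric(Sys.time() - t0, units = "secs")
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$results <- as.list(env)
  invisible(manifest)
}
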