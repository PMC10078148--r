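#' Write a gridded field to a self-describing JSON file
#'
#' Serialises a [GriddedField-class] as plain-text JSON carrying the variable
#' name, units, coordinate vectors, time axis and the data array with its
#' dimensions, at full double precision. The write/read round trip is
#' value-identical to within floating-point text representation (< 1e-12
#' relative) and metadata-identical.
#'
#' @param field a [GriddedField-class].
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
writeGridded <- function(field, path) {
  obj <- list(format = "fireburden-grid-1",
              name = field@name, units = field@units,
              lat = field@lat, lon = field@lon,
              time = field@time,
              dim = dim(field@data),
              data = as.vector(field@data))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a gridded field written by [writeGridded()]
#'
#' @param path JSON path.
#' @return a [GriddedField-class]. A missing or empty units attribute
#'   triggers a validation warning.
#' @export
readGridded <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !identical(obj$format, "fireburden-grid-1"))
    stop("not a fireburden gridded-field file: ", path)
  if (is.null(obj$units) || !nzchar(obj$units))
    warning("gridded field at ", path, " has no units attribute")
  tm <- as.data.frame(obj$time)
  if (!nrow(tm)) tm <- NULL
  GriddedField(array(obj$data, dim = obj$dim), obj$lat, obj$lon, tm,
               units = if (is.null(obj$units)) "" else obj$units,
               name = if (is.null(obj$name)) "" else obj$name)
}

#' Write/read fire detections as CSV
#'
#' @param detections detection data.frame (`date`, `lon`, `lat`,
#'   `confidence`, `persistent`).
#' @param path CSV path.
#' @return `path` (write) or the detection data.frame (read).
#' @export
writeDetections <- function(detections, path) {
  checkDetections(detections)
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d$persistent <- as.logical(d$persistent)
  checkDetections(d)
  d
}

#' Write region slabs as GeoJSON
#'
#' Emits one rectangular polygon feature per region (its column slab on the
#' grid), with `region` and `id` properties.
#'
#' @param demographics list from [generatePopulation()].
#' @param config the generating [WorldConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsGeojson <- function(demographics, config, path) {
  res <- config@resolution
  lat0 <- config@lat0 - res / 2
  lat1 <- config@lat0 + (config@nLat - 0.5) * res
  features <- lapply(seq_len(nrow(demographics$regions)), function(i) {
    r <- demographics$regions[i, ]
    w <- config@lon0 + (r$colStart - 1.5) * res
    e <- config@lon0 + (r$colEnd - 0.5) * res
    ring <- list(c(w, lat0), c(e, lat0), c(e, lat1), c(w, lat1), c(w, lat0))
    list(type = "Feature",
         properties = list(region = r$region, id = r$id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write/read a feature table as CSV
#' @param table feature table data.frame.
#' @param path CSV path.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain blocks `world` (slot overrides for
#' [worldConfig()]), `model` (overrides for [modelSpec()]), `scenarios` (a
#' list of scenario names or name/override blocks), and scalars `seed` and
#' `gemmParams` (path). Missing blocks fall back to package defaults. The
#' global seed propagates to the world and model specs unless they override
#' it.
#'
#' @param path YAML path.
#' @return list with elements `world` ([WorldConfig-class]), `model`
#'   ([ModelSpec-class]), `scenarios` (list of [ScenarioSpec-class]), `seed`,
#'   `gemmParams`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pipelineConfig(world = y$world, model = y$model, scenarios = y$scenarios,
                 seed = y$seed, gemmParams = y$gemmParams)
}

#' Assemble a pipeline configuration
#'
#' @param world named list of [worldConfig()] overrides or a
#'   [WorldConfig-class].
#' @param model named list of [modelSpec()] overrides or a
#'   [ModelSpec-class].
#' @param scenarios character vector of canonical scenario names (subset of
#'   `"control"`, `"target_deforestation"`, `"minimum_deforestation"`,
#'   `"average_climate"`) or a list of [ScenarioSpec-class] objects;
#'   `"control"` is always included.
#' @param seed global seed; propagates to world and model unless overridden.
#' @param gemmParams path to a GEMM parameter CSV (default: packaged
#'   synthetic table).
#' @return list as described in [readPipelineConfig()].
#' @export
pipelineConfig <- function(world = list(), model = list(),
                           scenarios = c("control", "target_deforestation",
                                         "minimum_deforestation",
                                         "average_climate"),
                           seed = 1L, gemmParams = NULL) {
  if (is.null(seed)) seed <- 1L
  if (!is(world, "WorldConfig")) {
    if (is.null(world)) world <- list()
    if (!("seed" %in% names(world))) world$seed <- seed
    world <- do.call(worldConfig, world)
  }
  if (!is(model, "ModelSpec")) {
    if (is.null(model)) model <- list()
    if (!("seed" %in% names(model))) model$seed <- seed
    model <- do.call(modelSpec, model)
  }
  if (is.character(scenarios) || is.null(scenarios))
    scenarios <- lapply(union("control", scenarios), canonicalScenario,
                        world = world)
  if (is.null(gemmParams))
    gemmParams <- system.file("extdata", "gemm_params_synthetic.csv",
                              package = "fireburden")
  list(world = world, model = model, scenarios = scenarios, seed = seed,
       gemmParams = gemmParams)
}

canonicalScenario <- function(name, world) {
  yrs <- world@startYear + seq_len(world@nYears) - 1L
  switch(name,
         control = scenarioSpec("control"),
         target_deforestation =
           scenarioSpec("target_deforestation",
                        defTotals = derivePolicyTarget()),
         minimum_deforestation =
           scenarioSpec("minimum_deforestation",
                        defPatternSourceYear =
                          yrs[which.min(world@defTrajectory)]),
         average_climate =
           scenarioSpec("average_climate", climateMode = "climatology"),
         stop("unknown canonical scenario: ", name))
}

writeCsvArtifact <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline end-to-end
#'
#' Orchestrates synthetic world generation, detection filtering and gridding,
#' feature building, chronological hold-out evaluation, perturbation
#' sensitivities, counterfactual scenarios, emission scaling, toy
#' particulate-matter fields, averted health burden, and a summary report.
#' Every stage writes its artifact into `outDir`, and a manifest records the
#' seed, configuration digest and MD5 of every artifact; a rerun with the
#' same configuration reproduces deterministic artifacts bit-identically.
#' Stages whose artifacts already exist are skipped (and reloaded) unless
#' `overwrite = TRUE`, so deleting one artifact reruns only the stages that
#' depend on it.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @param outDir artifact directory (created if needed).
#' @param overwrite if `TRUE`, rerun every stage.
#' @param evaluate if `TRUE` (default), run the chronological hold-out stage.
#' @return list with the main in-memory artifacts (`world`, `features`,
#'   `holdout`, `sensitivities`, `scenarioReport`, `burden`, paths in
#'   `paths`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        overwrite = FALSE, evaluate = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outDir, f)
  paths <- c(detections = pth("detections.csv"),
             features = pth("features.csv"),
             holdout = pth("holdout_metrics.csv"),
             sensitivity = pth("sensitivity.csv"),
             scenarios = pth("scenario_report.csv"),
             emissions = pth("emissions_control.json"),
             pm = pth("pm_control.json"),
             burden = pth("burden.csv"),
             manifest = pth("manifest.json"))
  world <- generateWorld(config$world)

  if (overwrite || !file.exists(paths["detections"])) {
    dets <- generateFireDetections(world)
    writeDetections(dets, paths["detections"])
  } else dets <- readDetections(paths["detections"])

  kept <- filterFireDetections(dets, 66,
                               persistentSourceCells(world)$cell,
                               config$world)
  counts <- gridMonthlyFireCounts(kept, world)

  if (overwrite || !file.exists(paths["features"])) {
    features <- buildFeatureTable(world, counts)
    writeFeatureTable(features, paths["features"])
  } else features <- readFeatureTable(paths["features"])

  holdout <- NULL
  if (evaluate && (overwrite || !file.exists(paths["holdout"]))) {
    holdout <- chronologicalHoldout(features, config$model)
    m <- holdout$metrics
    writeCsvArtifact(data.frame(pearson_r = m$pearson_r,
                                p_value = m$p_value,
                                r_squared = m$r_squared, rmse = m$rmse),
                     paths["holdout"])
  }

  ensemble <- trainFoldModels(features, spec = config$model)

  if (overwrite || !file.exists(paths["sensitivity"])) {
    curves <- lapply(c("temperature", "precipitation", "deforestation"),
                     function(f) perturbationSensitivity(ensemble, features, f))
    sens <- elasticitySummary(curves)
    writeCsvArtifact(sens, paths["sensitivity"])
  } else sens <- utils::read.csv(paths["sensitivity"])

  panels <- lapply(config$scenarios, function(sc)
    buildScenarioPanel(world, counts, sc))
  names(panels) <- vapply(config$scenarios, function(sc) sc@name, "")
  report <- predictScenarios(ensemble, panels)
  writeCsvArtifact(report, paths["scenarios"])

  # emissions and PM for control and the first non-control scenario
  predGrid <- function(panel) {
    gf <- counts
    gf@data[] <- 0
    pr <- predict(ensemble, panel)
    rr <- as.integer(sub("^r([0-9]+)c([0-9]+)$", "\\1", panel$cell))
    cc <- as.integer(sub("^r([0-9]+)c([0-9]+)$", "\\2", panel$cell))
    t <- match(paste(panel$year, panel$month),
               paste(gf@time$year, gf@time$month))
    nLat <- config$world@nLat
    nCellGrid <- nLat * config$world@nLon
    gf@data[(t - 1L) * nCellGrid + (cc - 1L) * nLat + rr] <- pr
    gf
  }
  mlControl <- predGrid(panels$control)
  finnControl <- emissionsFromCounts(mlControl, config$world@emissionFactor)
  writeGridded(finnControl, paths["emissions"])
  pmControl <- generatePmField(finnControl, config$world)
  writeGridded(pmControl, paths["pm"])

  burden <- NULL
  scenNames <- setdiff(names(panels), "control")
  if (length(scenNames)) {
    sc <- scenNames[1L]
    mlScen <- predGrid(panels[[sc]])
    finnScen <- scaleEmissions(mlControl, mlScen, finnControl)
    pmScen <- generatePmField(finnScen, config$world)
    demog <- generatePopulation(config$world)
    params <- loadGemmParams(config$gemmParams)
    lastYear <- max(pmControl@time$year)
    burden <- avertedBurden(fieldSlice(pmControl, lastYear),
                            fieldSlice(pmScen, lastYear), demog, params)
    writeCsvArtifact(burden, paths["burden"])
  }

  manifest <- list(seed = config$seed,
                   generated = "fireburden pipeline",
                   world = list(nLat = config$world@nLat,
                                nLon = config$world@nLon,
                                nYears = config$world@nYears,
                                seed = config$world@seed),
                   artifacts = as.list(tools::md5sum(
                     paths[file.exists(paths) & names(paths) != "manifest"])))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  list(world = world, features = features, holdout = holdout,
       sensitivities = sens, scenarioReport = report, burden = burden,
       paths = paths)
}
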