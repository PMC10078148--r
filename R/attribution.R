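#' Permutation feature importance
#'
#' Importance of a feature is the mean increase in prediction RMSE when that
#' feature's column is randomly shuffled within the evaluation table,
#' repeated `nRepeats` times. A feature the model provably ignores (e.g. a
#' constant column) has importance exactly zero. Per-year importances are
#' retained for box-plot style summaries.
#'
#' @param ensemble a [TrainedEnsemble-class] (or any object with a `predict`
#'   method over the table schema).
#' @param table evaluation feature table with a `fire_count` column.
#' @param features features to assess; defaults to the ensemble schema.
#' @param nRepeats number of shuffles per feature (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `feature`, `importance` (mean RMSE
#'   increase), `sd` (across repeats); attribute `"perYear"` holds a long
#'   data.frame `feature`, `year`, `repeat_id`, `importance`.
#' @export
permutationImportance <- function(ensemble, table,
                                  features = ensemble@featureNames,
                                  nRepeats = 20L, seed = 1L) {
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  base <- predict(ensemble, table)
  y <- table$fire_count
  yrs <- table$year
  rmse <- function(e) sqrt(mean(e^2))
  baseAll <- rmse(base - y)
  baseYear <- tapply((base - y)^2, yrs, function(v) sqrt(mean(v)))
  set.seed(seed)
  perYear <- list()
  res <- lapply(features, function(f) {
    imp <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      tab <- table
      if (length(unique(tab[[f]])) > 1L) {
        tab[[f]] <- sample(tab[[f]])
      }
      pr <- predict(ensemble, tab)
      imp[r] <- rmse(pr - y) - baseAll
      py <- tapply((pr - y)^2, yrs, function(v) sqrt(mean(v))) - baseYear
      perYear[[length(perYear) + 1L]] <<-
        data.frame(feature = f, year = as.integer(names(py)), repeat_id = r,
                   importance = as.numeric(py))
    }
    data.frame(feature = f, importance = mean(imp), sd = stats::sd(imp))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "perYear") <- do.call(rbind, perYear)
  out
}

#' Sensitivity curve from incremental feature perturbation
#'
#' Per-increment percent change in predicted annual-total fire count
#' (averaged across years), plus the normalised per-unit slope in reporting
#' units.
#'
#' @slot feature `"temperature"`, `"precipitation"` or `"deforestation"`.
#' @slot increments the increment grid (K for temperature, percent
#'   otherwise), strictly monotone.
#' @slot pctChange percent change in annual-total prediction per increment.
#' @slot rawSlope least-squares slope of mean log total-ratio against the
#'   increment coordinate (additive K for temperature, `log(1 + delta/100)`
#'   for the multiplicative features), fitted through the origin.
#' @slot slope normalised slope in the conventional reporting units: percent
#'   per +0.1 K, percent per percentage-point precipitation reduction, or
#'   percent per percentage-point deforestation increase (an elasticity).
#' @slot slopeUnits description of the reporting unit.
#' @export
setClass("SensitivityCurve",
  representation(feature = "character", increments = "numeric",
                 pctChange = "numeric", rawSlope = "numeric",
                 slope = "numeric", slopeUnits = "character"))

setMethod("show", "SensitivityCurve", function(object) {
  cat("SensitivityCurve for ", object@feature, ": slope ",
      format(object@slope, digits = 4), " ", object@slopeUnits, "\n",
      sep = "")
})

defaultIncrements <- function(feature) {
  switch(feature,
         temperature = seq(0.1, 1, by = 0.1),
         precipitation = -(1:10),
         deforestation = c(1, seq(5, 50, by = 5)),
         stop("unknown perturbation feature: ", feature))
}

applyPerturbation <- function(table, feature, delta) {
  if (feature == "temperature") {
    table$temperature <- table$temperature + delta
  } else if (feature == "precipitation") {
    fac <- 1 + delta / 100
    if (any(table$precip * fac <= 0))
      stop("input error: increment makes precipitation non-positive")
    table$precip <- table$precip * fac
    if ("precip_prev6" %in% names(table))
      table$precip_prev6 <- table$precip_prev6 * fac
  } else if (feature == "deforestation") {
    table$deforestation_3yr <- table$deforestation_3yr * (1 + delta / 100)
  } else stop("unknown perturbation feature: ", feature)
  table
}

#' Perturbation sensitivity of predicted fire count
#'
#' Re-runs prediction with one driver incremented in every cell-month of the
#' panel (temperature additively in K; precipitation and deforestation
#' multiplicatively in percent, with the antecedent precipitation window
#' scaled consistently), computes the percent change in annual-total
#' prediction averaged across years at each increment, and extracts a
#' per-unit sensitivity by a through-origin least-squares fit of the mean log
#' total-ratio against the increment coordinate. For multiplicative drivers
#' the coordinate is `log(1 + delta/100)`, so the raw slope is an elasticity;
#' for temperature it is the increment in K. Reported slopes use the
#' conventional units: percent per +0.1 K (`100*(exp(0.1*rawSlope)-1)`),
#' percent per percentage-point precipitation reduction (`-rawSlope`), and
#' percent per percentage-point deforestation increase (`rawSlope`).
#'
#' @param ensemble a [TrainedEnsemble-class] (or oracle stub with a `predict`
#'   method).
#' @param table the (unperturbed) feature panel.
#' @param feature `"temperature"`, `"precipitation"` or `"deforestation"`.
#' @param increments increment grid; defaults to +0.1..+1 K, -1..-10 percent,
#'   or +1..+50 percent respectively.
#' @return a [SensitivityCurve-class].
#' @export
perturbationSensitivity <- function(ensemble, table, feature,
                                    increments = defaultIncrements(feature)) {
  if (length(increments) < 1L)
    stop("at least one increment required")
  if (length(increments) > 1L && !(all(diff(increments) > 0) ||
                                   all(diff(increments) < 0)))
    stop("increment grid must be strictly monotone")
  base <- predict(ensemble, table)
  baseTotals <- tapply(base, table$year, sum)
  if (any(baseTotals <= 0))
    stop("baseline annual totals must be positive for sensitivity analysis")
  logRatio <- numeric(length(increments))
  pct <- numeric(length(increments))
  for (i in seq_along(increments)) {
    pr <- predict(ensemble, applyPerturbation(table, feature, increments[i]))
    totals <- tapply(pr, table$year, sum)
    lr <- log(totals / baseTotals)
    logRatio[i] <- mean(lr)
    pct[i] <- 100 * (exp(logRatio[i]) - 1)
  }
  x <- if (feature == "temperature") increments else log1p(increments / 100)
  rawSlope <- sum(x * logRatio) / sum(x * x)
  slope <- switch(feature,
                  temperature = 100 * (exp(0.1 * rawSlope) - 1),
                  precipitation = -rawSlope,
                  deforestation = rawSlope)
  units <- switch(feature,
                  temperature = "% per +0.1 K",
                  precipitation = "% per -1% precipitation",
                  deforestation = "% per +1% deforestation")
  new("SensitivityCurve", feature = feature,
      increments = as.numeric(increments), pctChange = pct,
      rawSlope = rawSlope, slope = slope, slopeUnits = units)
}

#' Summarise sensitivity curves into per-feature elasticities
#'
#' @param curves a list of [SensitivityCurve-class] objects (e.g. one per
#'   seed and feature).
#' @return data.frame with one row per feature: `feature`, `slope_mean`,
#'   `slope_sd`, `n`, `units`.
#' @export
elasticitySummary <- function(curves) {
  if (!length(curves)) stop("at least one curve required")
  feats <- vapply(curves, function(cu) cu@feature, "")
  slopes <- vapply(curves, function(cu) cu@slope, 0)
  units <- vapply(curves, function(cu) cu@slopeUnits, "")
  out <- do.call(rbind, lapply(unique(feats), function(f) {
    s <- slopes[feats == f]
    data.frame(feature = f, slope_mean = mean(s),
               slope_sd = if (length(s) > 1L) stats::sd(s) else 0,
               n = length(s), units = units[feats == f][1L])
  }))
  rownames(out) <- NULL
  out
}

#' Oracle stub model backed by the generative fire rate
#'
#' A model-like object whose predictions are the ground-truth expected fire
#' rate evaluated on the feature columns. Useful for validating the
#' perturbation and scenario machinery against known elasticities.
#'
#' @param params a [FireRateParams-class].
#' @return object of class `"fireOracle"` with a `predict` method taking a
#'   feature table (needs `temperature`, `precip`, `deforestation_3yr`,
#'   `pasture_frac`, `month`).
#' @export
oracleModel <- function(params = fireRateParams()) {
  structure(list(params = params), class = "fireOracle")
}

#' @rdname oracleModel
#' @param object a `"fireOracle"` object.
#' @param newdata feature table.
#' @param ... unused.
#' @exportS3Method stats::predict
predict.fireOracle <- function(object, newdata, ...) {
  expectedFireRate(newdata$temperature, newdata$precip,
                   newdata$deforestation_3yr, newdata$pasture_frac / 100,
                   newdata$month, object$params)
}

#' Run the full sensitivity-recovery study
#'
#' The package's headline experiment: for each seed, generate the default
#' synthetic world, filter and grid detections, build the full
#' (climate + land-use + deforestation) feature panel, train the boosted
#' trees + neural network ensemble with fold-wise cross-validation, and run
#' the three incremental perturbation sweeps. Returns the per-feature
#' sensitivity summary across seeds.
#'
#' @param seeds integer seeds; one world and ensemble per seed.
#' @param config base [WorldConfig-class] (the seed slot is replaced per
#'   run).
#' @param spec base [ModelSpec-class] (seed replaced per run).
#' @param features perturbation features to sweep.
#' @param featureSet feature set of the panel.
#' @return list with `summary` (per-feature mean/sd slopes across seeds, see
#'   [elasticitySummary()]), `curves` (all [SensitivityCurve-class]s) and
#'   `nRows` (panel rows per seed).
#' @export
runSensitivityStudy <- function(seeds = 1:5, config = worldConfig(),
                                spec = modelSpec(),
                                features = c("deforestation", "temperature",
                                             "precipitation"),
                                featureSet = "clim_lu_def") {
  curves <- list()
  nRows <- NA_integer_
  for (s in seeds) {
    cfg <- config; cfg@seed <- as.integer(s)
    sp <- spec; sp@seed <- as.integer(s)
    w <- generateWorld(cfg)
    dets <- generateFireDetections(w)
    kept <- filterFireDetections(dets, 66, persistentSourceCells(w)$cell, cfg)
    counts <- gridMonthlyFireCounts(kept, w)
    tab <- buildFeatureTable(w, counts, featureSet = featureSet)
    ens <- trainFoldModels(tab, spec = sp)
    for (f in features)
      curves[[length(curves) + 1L]] <- perturbationSensitivity(ens, tab, f)
    nRows <- nrow(tab)
  }
  list(summary = elasticitySummary(curves), curves = curves, nRows = nRows)
}
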