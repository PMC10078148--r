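#' Model specification for the fire-count ensemble
#'
#' Families, hyperparameter grids and the cross-validation protocol used by
#' [trainFoldModels()]. The default reported ensemble averages gradient
#' boosted trees (`"xgb"`) and a feed-forward neural network (`"nn"`); a
#' random forest (`"rf"`, via the ranger package) is available but excluded
#' from the default family set. Grids are lists of named hyperparameter
#' lists; with a single grid point the search degenerates to that point.
#'
#' @slot families character subset of `c("xgb", "nn", "rf")`.
#' @slot xgbGrid,nnGrid,rfGrid non-empty lists of hyperparameter lists.
#' @slot nFolds number of cross-validation folds (>= 2).
#' @slot seed integer seed controlling fold assignment and fits.
#' @slot logTarget if `TRUE`, fit on `log1p(count)` and back-transform
#'   (default `FALSE`: squared error on raw counts).
#' @export
setClass("ModelSpec",
  representation(families = "character", xgbGrid = "list", nnGrid = "list",
                 rfGrid = "list", nFolds = "integer", seed = "integer",
                 logTarget = "logical"),
  prototype(
    families = c("xgb", "nn"),
    xgbGrid = list(list(nrounds = 150, eta = 0.1, max_depth = 6,
                        subsample = 0.8, colsample_bytree = 0.9,
                        min_child_weight = 5)),
    nnGrid = list(list(size = 16, decay = 1e-4, maxit = 150)),
    rfGrid = list(list(num.trees = 200, mtry = NULL, min.node.size = 5)),
    nFolds = 5L, seed = 1L, logTarget = FALSE
  )
)

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!length(object@families) ||
      !all(object@families %in% c("xgb", "nn", "rf")))
    msgs <- c(msgs, "families must be a subset of xgb, nn, rf")
  if (object@nFolds < 2L) msgs <- c(msgs, "nFolds must be >= 2")
  for (g in c("xgbGrid", "nnGrid", "rfGrid"))
    if (!length(slot(object, g))) msgs <- c(msgs, paste(g, "must be non-empty"))
  if (length(msgs)) msgs else TRUE
})

#' @rdname ModelSpec-class
#' @param ... slot overrides.
#' @export
modelSpec <- function(...) {
  args <- list(...)
  for (s in c("nFolds", "seed"))
    if (s %in% names(args)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("ModelSpec"), args))
}

#' Trained fold-wise ensemble
#'
#' Holds one fitted member per family and fold, the selected hyperparameters,
#' the feature schema and the training years. Prediction is the mean over
#' members of the included families, clipped below at zero.
#'
#' @slot members list of member fits (each a list with `family`, `fold`,
#'   `fit`, and for the neural network the feature/target scalers).
#' @slot featureNames character feature schema.
#' @slot families families included at prediction time.
#' @slot trainYears integer years the ensemble was trained on.
#' @slot hyperparameters selected grid point per family.
#' @slot spec the generating [ModelSpec-class].
#' @export
setClass("TrainedEnsemble",
  representation(members = "list", featureNames = "character",
                 families = "character", trainYears = "integer",
                 hyperparameters = "list", spec = "ModelSpec"))

setMethod("show", "TrainedEnsemble", function(object) {
  cat("TrainedEnsemble: ", length(object@members), " members (",
      paste(object@families, collapse = " + "), "), ",
      length(object@featureNames), " features, years ",
      paste(range(object@trainYears), collapse = "-"), "\n", sep = "")
})

fitMember <- function(family, X, y, hp, seed) {
  set.seed(seed)
  if (family == "xgb") {
    dm <- xgboost::xgb.DMatrix(X, label = y)
    params <- list(eta = hp$eta, max_depth = hp$max_depth,
                   subsample = hp$subsample,
                   colsample_bytree = hp$colsample_bytree,
                   min_child_weight = hp$min_child_weight,
                   objective = "reg:squarederror", nthread = 1)
    fit <- xgboost::xgb.train(params = params, data = dm,
                              nrounds = hp$nrounds, verbose = 0)
    list(family = family, fit = fit)
  } else if (family == "nn") {
    mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    ysd <- stats::sd(y); if (!is.finite(ysd) || ysd == 0) ysd <- 1
    fit <- nnet::nnet(Xs, y / ysd, size = hp$size, linout = TRUE,
                      decay = hp$decay, maxit = hp$maxit, trace = FALSE,
                      MaxNWts = 10000)
    list(family = family, fit = fit, center = mu, scale = sdv, ysd = ysd)
  } else if (family == "rf") {
    if (!requireNamespace("ranger", quietly = TRUE))
      stop("the ranger package is required for random-forest members")
    df <- as.data.frame(X); df$.y <- y
    mtry <- hp$mtry
    if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
    fit <- ranger::ranger(.y ~ ., data = df, num.trees = hp$num.trees,
                          mtry = mtry, min.node.size = hp$min.node.size,
                          seed = seed, num.threads = 1)
    list(family = family, fit = fit)
  } else stop("unknown family: ", family)
}

predictMember <- function(member, X) {
  if (member$family == "const") {
    rep(member$value, nrow(X))
  } else if (member$family == "xgb") {
    as.numeric(predict(member$fit, xgboost::xgb.DMatrix(X)))
  } else if (member$family == "nn") {
    Xs <- sweep(sweep(X, 2, member$center), 2, member$scale, "/")
    as.numeric(predict(member$fit, Xs)) * member$ysd
  } else {
    as.numeric(predict(member$fit, as.data.frame(X))$predictions)
  }
}

gridFor <- function(spec, family) {
  switch(family, xgb = spec@xgbGrid, nn = spec@nnGrid, rf = spec@rfGrid)
}

#' Train the fold-wise ensemble
#'
#' Assigns rows to `nFolds` random folds (seeded), selects a hyperparameter
#' grid point per family by mean validation RMSE across folds, then fits one
#' member per family and fold on that fold's complement. With a single grid
#' point the search returns it without evaluation.
#'
#' @param table feature table (from [buildFeatureTable()]) restricted to the
#'   training years.
#' @param trainYears integer years the table must cover (protocol guard): a
#'   row outside `trainYears` is an error.
#' @param spec a [ModelSpec-class].
#' @return a [TrainedEnsemble-class].
#' @export
trainFoldModels <- function(table, trainYears = sort(unique(table$year)),
                            spec = modelSpec()) {
  validObject(spec)
  if (!length(trainYears)) stop("protocol error: trainYears is empty")
  if (!all(table$year %in% trainYears))
    stop("leakage error: table contains rows outside trainYears")
  featureNames <- setdiff(names(table),
                          c("cell", "lon", "lat", "year", "month",
                            "fire_count"))
  X <- as.matrix(table[, featureNames, drop = FALSE])
  yRaw <- table$fire_count
  y <- if (spec@logTarget) log1p(yRaw) else yRaw
  n <- nrow(X)
  set.seed(spec@seed)
  folds <- sample(rep_len(seq_len(spec@nFolds), n))
  if (any(tabulate(folds, spec@nFolds) == 0L))
    stop("protocol error: a fold has zero rows")

  chosen <- list()
  for (family in spec@families) {
    grid <- gridFor(spec, family)
    if (length(grid) == 1L) {
      chosen[[family]] <- grid[[1L]]
      next
    }
    errs <- vapply(seq_along(grid), function(g) {
      mean(vapply(seq_len(spec@nFolds), function(f) {
        tr <- folds != f
        m <- fitMember(family, X[tr, , drop = FALSE], y[tr], grid[[g]],
                       spec@seed + 131L * g + f)
        pr <- predictMember(m, X[!tr, , drop = FALSE])
        sqrt(mean((pr - y[!tr])^2))
      }, 0))
    }, 0)
    chosen[[family]] <- grid[[which.min(errs)]]
  }

  members <- list()
  for (family in spec@families) {
    for (f in seq_len(spec@nFolds)) {
      tr <- folds != f
      m <- fitMember(family, X[tr, , drop = FALSE], y[tr], chosen[[family]],
                     spec@seed + 1000L * match(family, spec@families) + f)
      m$fold <- f
      members[[length(members) + 1L]] <- m
    }
  }
  new("TrainedEnsemble", members = members, featureNames = featureNames,
      families = spec@families, trainYears = as.integer(sort(trainYears)),
      hyperparameters = chosen, spec = spec)
}

#' Predict fire counts with a trained ensemble
#'
#' The prediction is the mean of member predictions over the included
#' families, clipped below at zero (counts cannot be negative).
#'
#' @param object a [TrainedEnsemble-class].
#' @param newdata feature table or numeric matrix matching the schema.
#' @param families optional subset of families to average over.
#' @return numeric vector of predicted counts.
#' @export
setMethod("predict", "TrainedEnsemble",
  function(object, newdata, families = object@families) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object@featureNames, names(newdata))
    if (length(miss))
      stop("feature schema mismatch; missing: ", paste(miss, collapse = ", "))
    X <- as.matrix(newdata[, object@featureNames, drop = FALSE])
  } else {
    X <- newdata
    if (!identical(colnames(X), object@featureNames))
      stop("feature schema mismatch")
  }
  use <- Filter(function(m) m$family %in% families, object@members)
  if (!length(use)) stop("no members in requested families")
  preds <- lapply(use, function(m) predictMember(m, X))
  p <- rowMeans(do.call(cbind, preds))
  if (object@spec@logTarget) p <- expm1(p)
  pmax(p, 0)
})

#' Skill metrics on annual totals
#'
#' Aggregates observed and predicted series to totals per group (year) and
#' computes Pearson's r with its t-distribution p-value, the coefficient of
#' determination `r2 = 1 - SSres/SStot` (which can be negative when the
#' prediction is worse than the observed mean), and the RMSE in count units.
#'
#' @param observed,predicted equal-length numeric vectors (row-level).
#' @param grouping grouping vector (typically the year), >= 3 groups.
#' @return list with `pearson_r`, `p_value`, `r_squared`, `rmse`, `n_groups`,
#'   and the per-group `totals` data.frame.
#' @export
annualMetrics <- function(observed, predicted, grouping) {
  if (length(observed) != length(predicted) ||
      length(observed) != length(grouping))
    stop("observed, predicted and grouping must have equal length")
  obs <- tapply(observed, grouping, sum)
  pre <- tapply(predicted, grouping, sum)
  ng <- length(obs)
  if (ng < 3L) stop("need >= 3 groups for annual metrics")
  if (stats::sd(pre) == 0 || stats::sd(obs) == 0) {
    r <- NA_real_
    p <- NA_real_
  } else {
    r <- stats::cor(obs, pre)
    tt <- r * sqrt((ng - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = ng - 2)
  }
  ssres <- sum((obs - pre)^2)
  sstot <- sum((obs - mean(obs))^2)
  list(pearson_r = unname(r), p_value = unname(p),
       r_squared = unname(1 - ssres / sstot),
       rmse = sqrt(mean((obs - pre)^2)), n_groups = ng,
       totals = data.frame(group = names(obs), observed = as.numeric(obs),
                           predicted = as.numeric(pre)))
}

#' Chronological leave-one-year-out evaluation
#'
#' For each usable year, trains an ensemble on all other years and predicts
#' the held-out year, so every reported prediction is out-of-sample in time;
#' concatenated predictions cover each year exactly once. Returns the
#' held-out predictions and skill metrics on annual totals.
#'
#' @param table feature table covering >= 3 years.
#' @param spec a [ModelSpec-class].
#' @return list with `predictions` (data.frame `cell`, `year`, `month`,
#'   `observed`, `predicted`) and `metrics` (see [annualMetrics()]).
#' @export
chronologicalHoldout <- function(table, spec = modelSpec()) {
  years <- sort(unique(table$year))
  if (length(years) < 3L) stop("need >= 3 usable years")
  preds <- vector("list", length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    trainTab <- table[table$year != y, , drop = FALSE]
    testTab <- table[table$year == y, , drop = FALSE]
    ens <- trainFoldModels(trainTab, setdiff(years, y), spec)
    if (y %in% ens@trainYears)
      stop("leakage error: held-out year present in training years")
    preds[[i]] <- data.frame(cell = testTab$cell, year = testTab$year,
                             month = testTab$month,
                             observed = testTab$fire_count,
                             predicted = predict(ens, testTab))
  }
  predictions <- do.call(rbind, preds)
  list(predictions = predictions,
       metrics = annualMetrics(predictions$observed, predictions$predicted,
                               predictions$year))
}
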