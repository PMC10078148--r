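# Small worlds and specs shared across test files. Built once per test run.

tinyConfig <- function(seed = 1L, ...) {
  worldConfig(seed = seed, nLat = 6L, nLon = 8L, nYears = 4L,
              defTrajectory = c(120, 90, 50, 100), ...)
}

smallSpec <- function(seed = 1L, ...) {
  modelSpec(seed = seed,
            xgbGrid = list(list(nrounds = 60, eta = 0.15, max_depth = 4,
                                subsample = 0.8, colsample_bytree = 0.9,
                                min_child_weight = 5)),
            nnGrid = list(list(size = 6, decay = 1e-4, maxit = 60)),
            nFolds = 3L, ...)
}

# cache the tiny world pipeline (world, detections, counts, features) once
.fixtures <- new.env(parent = emptyenv())

tinyWorld <- function() {
  if (is.null(.fixtures$world)) .fixtures$world <- generateWorld(tinyConfig())
  .fixtures$world
}

tinyDetections <- function() {
  if (is.null(.fixtures$dets))
    .fixtures$dets <- generateFireDetections(tinyWorld())
  .fixtures$dets
}

tinyCounts <- function() {
  if (is.null(.fixtures$counts)) {
    w <- tinyWorld()
    kept <- filterFireDetections(tinyDetections(), 66,
                                 persistentSourceCells(w)$cell, w@config)
    .fixtures$counts <- gridMonthlyFireCounts(kept, w)
  }
  .fixtures$counts
}

tinyTable <- function(featureSet = "clim_lu_def") {
  key <- paste0("tab_", featureSet)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- buildFeatureTable(tinyWorld(), tinyCounts(),
                                          featureSet = featureSet)
  .fixtures[[key]]
}

# ensemble of constant stub members, for averaging-contract tests
constEnsemble <- function(values, featureNames = c("precip", "temperature")) {
  members <- lapply(values, function(v) list(family = "const", value = v,
                                             fold = 1L))
  new("TrainedEnsemble", members = members, featureNames = featureNames,
      families = "const", trainYears = 1L, hyperparameters = list(),
      spec = modelSpec())
}

# two-region demographic fixture on an r x c grid with uniform population
flatDemographics <- function(nr = 4L, nc = 6L, total = 1e5,
                             mortality = 0.01, yll = 0.2, yld = 0.06) {
  pop <- matrix(total / (nr * nc), nr, nc)
  half <- nc %/% 2L
  regionField <- matrix(rep(c(1L, 2L), c(nr * half, nr * (nc - half))),
                        nr, nc)
  ages <- c("25-64" = 1)
  rates <- data.frame(region = rep(c("A", "B"), each = 1),
                      outcome = "ncd_lri", age = "25-64",
                      mortality = mortality, yll = yll, yld = yld)
  list(population = GriddedField(pop, lat = seq_len(nr), lon = seq_len(nc),
                                 units = "persons", name = "population"),
       ageFractions = ages,
       baselineRates = rates,
       regionField = regionField,
       regions = data.frame(region = c("A", "B"), id = 1:2,
                            colStart = c(1L, half + 1L),
                            colEnd = c(half, nc)))
}

# GEMM table with the logistic weight forced on (mu_w very negative), so
# RR = exp(theta * log(1 + z/alpha)) in closed form
simpleGemm <- function(theta = 0.2, se = 0.02, alpha = 1.6,
                       ages = "25-64", z0 = 2.4) {
  params <- data.frame(outcome = "ncd_lri", age = ages, theta = theta,
                       theta_se = se, alpha = alpha, mu_w = -1e6, nu_w = 1)
  attr(params, "z0") <- z0
  params
}
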