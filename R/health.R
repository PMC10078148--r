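#' Load GEMM hazard-function parameters
#'
#' Reads a parameter table for the Global Exposure Mortality Model (GEMM)
#' hazard function: one row per outcome and age group with columns `outcome`,
#' `age`, `theta`, `theta_se`, `alpha`, `mu_w`, `nu_w`. The packaged default
#' (`gemm_params_synthetic.csv`) is a synthetic stand-in table using a single
#' published-magnitude parameter set replicated across adult age groups; real
#' GEMM supplement tables can be dropped in with the same columns.
#'
#' @param path CSV path; defaults to the packaged synthetic table.
#' @param z0 counterfactual threshold (ug/m3) below which no excess risk is
#'   assumed; default 2.4.
#' @return data.frame with the parameter columns and a `z0` attribute.
#' @export
loadGemmParams <- function(path = system.file("extdata",
                                              "gemm_params_synthetic.csv",
                                              package = "fireburden"),
                           z0 = 2.4) {
  params <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("outcome", "age", "theta", "theta_se", "alpha", "mu_w", "nu_w")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("configuration error: GEMM table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(params$theta <= 0))
    stop("configuration error: theta must be > 0")
  if (z0 < 0) stop("configuration error: z0 must be >= 0")
  attr(params, "z0") <- z0
  params
}

gemmRow <- function(params, outcome, age) {
  i <- which(params$outcome == outcome & params$age == age)
  if (length(i) != 1L)
    stop("configuration error: no GEMM parameter row for outcome '",
         outcome, "', age '", age, "'")
  params[i, ]
}

#' GEMM relative risk of long-term PM2.5 exposure
#'
#' Evaluates the GEMM hazard function
#' `RR = exp(theta * log(1 + z/alpha) * omega(z))` with
#' `z = max(0, pm - z0)` and the logistic weight
#' `omega(z) = 1 / (1 + exp(-(z - mu_w)/nu_w))`. RR equals 1 at and below the
#' counterfactual threshold and is continuous and strictly increasing above
#' it. The `lower`/`upper` tiers evaluate at `theta -/+ 1.96 * theta_se`.
#'
#' @param pm annual-mean PM2.5 (ug/m3), >= 0; vectorised.
#' @param params GEMM parameter table from [loadGemmParams()].
#' @param outcome,age stratum selecting the parameter row.
#' @param tier `"mean"`, `"lower"` or `"upper"`.
#' @return relative risk, same length as `pm`.
#' @export
gemmRelativeRisk <- function(pm, params, outcome = "ncd_lri",
                             age = params$age[1L],
                             tier = c("mean", "lower", "upper")) {
  tier <- match.arg(tier)
  if (any(pm < 0)) stop("pm must be >= 0")
  row <- gemmRow(params, outcome, age)
  theta <- switch(tier, mean = row$theta,
                  lower = row$theta - 1.96 * row$theta_se,
                  upper = row$theta + 1.96 * row$theta_se)
  z0 <- attr(params, "z0")
  if (is.null(z0)) z0 <- 2.4
  z <- pmax(0, pm - z0)
  omega <- 1 / (1 + exp(-(z - row$mu_w) / row$nu_w))
  exp(theta * log1p(z / row$alpha) * omega)
}

#' Morbidity adjustment of a relative risk
#'
#' Shrinks a mortality relative risk toward 1 for morbidity outcomes:
#' `RR_adjusted = ratio * RR - ratio + 1`. Ratios of 0.141 (ischemic heart
#' disease) and 0.553 (stroke) are conventional; ratio 1 is the identity and
#' ratio 0 the null.
#'
#' @param rr relative risk, >= 1.
#' @param ratio adjustment ratio in `[0, 1]`.
#' @return adjusted relative risk.
#' @export
adjustRrForMorbidity <- function(rr, ratio) {
  if (any(rr < 1)) stop("rr must be >= 1")
  if (any(ratio < 0 | ratio > 1)) stop("ratio must be in [0, 1]")
  ratio * rr - ratio + 1
}

#' Attributable burden from a relative risk
#'
#' The standard attributable-burden form
#' `burden = pop * baseRate * (1 - 1/RR)`, applied identically to deaths
#' (mortality rates), years of life lost (YLL rates) and years lived with
#' disability (YLD rates, with a morbidity-adjusted RR where configured).
#'
#' @param pop exposed population (persons), >= 0.
#' @param baseRate baseline rate (events per person per year), >= 0.
#' @param rr relative risk, >= 1.
#' @return events per year.
#' @export
attributableBurden <- function(pop, baseRate, rr) {
  if (any(pop < 0) || any(baseRate < 0)) stop("pop and baseRate must be >= 0")
  if (any(rr < 1)) stop("rr must be >= 1")
  pop * baseRate * (1 - 1 / rr)
}

#' Disability-adjusted life years
#'
#' @param yll years of life lost, >= 0.
#' @param yld years lived with disability, >= 0.
#' @return `yll + yld`, exactly.
#' @export
computeDalys <- function(yll, yld) {
  if (any(yll < 0) || any(yld < 0)) stop("yll and yld must be >= 0")
  yll + yld
}

# cell-level attributable burden array for one exposure field:
# list of matrices deaths/yll/yld per (outcome, age, tier)
cellBurden <- function(pm, demographics, params, outcome, age, tier,
                       yldRatio = 1) {
  rr <- gemmRelativeRisk(as.vector(pm), params, outcome, age, tier)
  popAge <- demographics$population@data * demographics$ageFractions[[age]]
  reg <- demographics$regionField
  rates <- demographics$baselineRates
  regNames <- demographics$regions$region
  mort <- matrix(0, nrow(pm), ncol(pm))
  yll <- mort; yld <- mort
  rrm <- matrix(rr, nrow(pm), ncol(pm))
  rrAdj <- adjustRrForMorbidity(rrm, yldRatio)
  for (i in seq_along(regNames)) {
    sel <- reg == i
    rw <- rates[rates$region == regNames[i] & rates$outcome == outcome &
                  rates$age == age, ]
    if (nrow(rw) != 1L)
      stop("configuration error: no baseline-rate row for region '",
           regNames[i], "', outcome '", outcome, "', age '", age, "'")
    mort[sel] <- attributableBurden(popAge[sel], rw$mortality, rrm[sel])
    yll[sel] <- attributableBurden(popAge[sel], rw$yll, rrm[sel])
    yld[sel] <- attributableBurden(popAge[sel], rw$yld, rrAdj[sel])
  }
  list(deaths = mort, yll = yll, yld = yld)
}

#' Averted health burden between two exposure fields (subtraction method)
#'
#' Computes the PM2.5-attributable burden cell-wise under the control and the
#' scenario exposure fields and subtracts: `averted = burden(control) -
#' burden(scenario)` per cell, outcome, age group and GEMM tier, then
#' aggregates by region. The result is antisymmetric under swapping the two
#' fields and zero when they are identical; uncertainty is propagated by
#' evaluating the whole chain at the three GEMM tiers, so
#' `lower <= mean <= upper` stratum-wise whenever `theta_se > 0`.
#'
#' @param pmControl,pmScenario matrices (lat x lon) of annual-mean PM2.5
#'   (ug/m3) on the population grid.
#' @param demographics list from [generatePopulation()].
#' @param params GEMM parameter table from [loadGemmParams()].
#' @param outcomes outcomes to evaluate (default all in the baseline-rate
#'   table).
#' @param yldRatios named morbidity-adjustment ratios per outcome (default 1,
#'   i.e. no adjustment, for outcomes not named).
#' @return a burden table: data.frame with one row per region x outcome x
#'   age (plus `"total"` region rows) and columns
#'   `<metric>_<tier>` for metrics deaths, yll, yld, dalys, and per-100,000
#'   rate columns `deaths_rate_<tier>` and `dalys_rate_<tier>` (NA for
#'   zero-population strata). DALYs equal YLL + YLD exactly per stratum.
#' @export
avertedBurden <- function(pmControl, pmScenario, demographics, params,
                          outcomes = unique(demographics$baselineRates$outcome),
                          yldRatios = NULL) {
  if (!identical(dim(pmControl), dim(pmScenario)) ||
      !identical(dim(pmControl), dim(demographics$population@data)))
    stop("alignment error: exposure and population grids differ")
  ages <- unique(demographics$baselineRates$age)
  tiers <- c("mean", "lower", "upper")
  reg <- demographics$regionField
  regNames <- demographics$regions$region
  pop <- demographics$population@data
  regPop <- vapply(seq_along(regNames), function(i) sum(pop[reg == i]), 0)

  rows <- list()
  for (outcome in outcomes) {
    ratio <- if (!is.null(yldRatios) && outcome %in% names(yldRatios))
      yldRatios[[outcome]] else 1
    for (age in ages) {
      res <- list()
      for (tier in tiers) {
        bc <- cellBurden(pmControl, demographics, params, outcome, age, tier,
                         ratio)
        bs <- cellBurden(pmScenario, demographics, params, outcome, age, tier,
                         ratio)
        av <- list(deaths = bc$deaths - bs$deaths, yll = bc$yll - bs$yll,
                   yld = bc$yld - bs$yld)
        av$dalys <- computeDalysSigned(av$yll, av$yld)
        res[[tier]] <- av
      }
      for (i in seq_along(regNames)) {
        sel <- reg == i
        row <- data.frame(region = regNames[i], outcome = outcome, age = age)
        for (metric in c("deaths", "yll", "yld", "dalys"))
          for (tier in tiers)
            row[[paste0(metric, "_", tier)]] <- sum(res[[tier]][[metric]][sel])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  aggregateByRegion(out, regPop = stats::setNames(regPop, regNames))
}

# DALY additivity without the non-negativity guard: averted strata can be
# negative when the scenario is dirtier than the control.
computeDalysSigned <- function(yll, yld) yll + yld

#' Aggregate a stratum burden table by region and attach per-100,000 rates
#'
#' Appends domain-total rows (region `"total"`) and per-100,000 rate columns
#' for deaths and DALYs, computed against regional population. Zero-population
#' regions get `NA` rates rather than a division error.
#'
#' @param burden stratum data.frame as built by [avertedBurden()] (columns
#'   `region`, `outcome`, `age` and `<metric>_<tier>`).
#' @param regPop named numeric vector of population per region.
#' @return the burden table with total rows and rate columns.
#' @export
aggregateByRegion <- function(burden, regPop) {
  metricCols <- setdiff(names(burden), c("region", "outcome", "age"))
  tot <- do.call(rbind, lapply(split(burden, burden[, c("outcome", "age")],
                                     drop = TRUE), function(d) {
    row <- d[1L, ]
    row$region <- "total"
    for (cl in metricCols) row[[cl]] <- sum(d[[cl]])
    row
  }))
  out <- rbind(burden, tot)
  rownames(out) <- NULL
  popFor <- function(region) {
    if (region == "total") sum(regPop) else unname(regPop[region])
  }
  for (metric in c("deaths", "dalys")) for (tier in c("mean", "lower", "upper")) {
    src <- paste0(metric, "_", tier)
    dst <- paste0(metric, "_rate_", tier)
    p <- vapply(out$region, popFor, 0)
    out[[dst]] <- ifelse(p > 0, 1e5 * out[[src]] / p, NA_real_)
  }
  out
}

#' Population-weighted mean PM2.5
#'
#' @param pm matrix of PM2.5 (ug/m3).
#' @param population matrix of persons on the same grid.
#' @param mask optional logical matrix restricting to a region.
#' @return weighted mean (ug/m3); errors if the selected population is zero.
#' @export
populationWeightedMean <- function(pm, population, mask = NULL) {
  if (!identical(dim(pm), dim(population)))
    stop("alignment error: pm and population grids differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pm), ncol(pm))
  w <- population[mask]
  if (sum(w) <= 0) stop("region population must be > 0")
  sum(pm[mask] * w) / sum(w)
}
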