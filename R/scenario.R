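#' Counterfactual scenario specification
#'
#' Declarative description of a scenario: exactly one deforestation rule and
#' one climate mode are active. Canonical scenarios:
#' * `control` — observed deforestation, observed climate;
#' * `minimum_deforestation` — the gridded deforestation of the minimum-total
#'   year copied into every scenario year, observed climate;
#' * `target_deforestation` — observed spatial pattern of each scenario year
#'   rescaled so its biome total equals the policy target, observed climate;
#' * `average_climate` — observed deforestation, climate features replaced by
#'   their monthly climatology in the scenario years.
#'
#' @slot name scenario name.
#' @slot defTotals annual deforestation total override (km2/yr): a single
#'   value recycled over scenario years, or one value per scenario year;
#'   `NA` for no override.
#' @slot defPatternSourceYear calendar year whose gridded pattern is copied
#'   into every scenario year (`NA` for none).
#' @slot climateMode `"observed"` or `"climatology"`.
#' @slot climatologyYears calendar years the climatology averages over
#'   (default: all world years).
#' @slot scenarioYears calendar years the overrides apply to.
#' @export
setClass("ScenarioSpec",
  representation(name = "character", defTotals = "numeric",
                 defPatternSourceYear = "integer", climateMode = "character",
                 climatologyYears = "integer", scenarioYears = "integer"),
  prototype(name = "control", defTotals = NA_real_,
            defPatternSourceYear = NA_integer_, climateMode = "observed",
            climatologyYears = integer(), scenarioYears = integer()))

setValidity("ScenarioSpec", function(object) {
  msgs <- character()
  defRules <- c(totals = !all(is.na(object@defTotals)),
                pattern = !is.na(object@defPatternSourceYear))
  if (sum(defRules) > 1L)
    msgs <- c(msgs, "at most one deforestation rule may be active")
  if (!object@climateMode %in% c("observed", "climatology"))
    msgs <- c(msgs, "climateMode must be 'observed' or 'climatology'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScenarioSpec-class
#' @param name scenario name.
#' @param ... slot overrides.
#' @export
scenarioSpec <- function(name = "control", ...) {
  args <- list(...)
  for (s in c("defPatternSourceYear", "climatologyYears", "scenarioYears"))
    if (s %in% names(args)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("ScenarioSpec", name = name), args))
}

#' Pattern-preserving rescaling of an annual deforestation grid
#'
#' Multiplies every cell by `targetTotal / observedTotal` so the spatial
#' pattern is retained exactly while the (masked) total matches the target.
#'
#' @param grid matrix (km2 per cell) for one year.
#' @param targetTotal desired total (km2).
#' @param mask optional logical matrix; the total is taken over masked cells
#'   (unmasked cells are scaled by the same factor).
#' @return the rescaled matrix.
#' @export
scaleDeforestationToTotal <- function(grid, targetTotal, mask = NULL) {
  tot <- if (is.null(mask)) sum(grid) else sum(grid[mask])
  if (tot <= 0) {
    if (targetTotal == 0) return(grid)
    stop("undefined-pattern error: observed total is zero with non-zero target")
  }
  grid * (targetTotal / tot)
}

#' Deforestation policy target for the biome
#'
#' Reduces a Legal-Amazon-wide annual target by the percent area difference
#' between the Legal Amazon and the biome. The result is reported to one
#' decimal, truncated toward zero (matching the published reporting
#' convention for this quantity).
#'
#' @param blaTarget target for the Brazilian Legal Amazon (km2/yr);
#'   default 3925.
#' @param areaDifference percent area difference in `[0, 100)`;
#'   default 16.34.
#' @return biome-level target (km2/yr), one decimal.
#' @examples
#' derivePolicyTarget()            # 3283.6
#' derivePolicyTarget(1000, 50)    # 500
#' @export
derivePolicyTarget <- function(blaTarget = 3925, areaDifference = 16.34) {
  if (areaDifference < 0 || areaDifference >= 100)
    stop("areaDifference must be in [0, 100)")
  trunc(blaTarget * (1 - areaDifference / 100) * 10) / 10
}

#' Monthly climatology of a gridded field
#'
#' Per cell and calendar month, the mean over the period years. Invariant to
#' the ordering of years.
#'
#' @param field monthly [GriddedField-class].
#' @param periodYears calendar years to average over (>= 2 years).
#' @return [GriddedField-class] with 12 time slices (`year` is `NA`).
#' @export
climatologicalClimate <- function(field,
                                  periodYears = unique(field@time$year)) {
  periodYears <- sort(unique(periodYears))
  if (length(periodYears) < 2L) stop("climatology period must cover >= 2 years")
  if (!all(periodYears %in% field@time$year))
    stop("period years missing from the field time axis")
  nr <- length(field@lat); nc <- length(field@lon)
  clim <- array(0, c(nr, nc, 12L))
  for (m in 1:12) {
    idx <- which(field@time$month == m & field@time$year %in% periodYears)
    s <- matrix(0, nr, nc)
    for (t in idx) s <- s + field@data[, , t]
    clim[, , m] <- s / length(idx)
  }
  GriddedField(clim, field@lat, field@lon,
               data.frame(year = NA_integer_, month = 1:12),
               field@units, paste0(field@name, "_climatology"))
}

applyScenarioToWorld <- function(world, spec) {
  cfg <- world@config
  yrs <- annualTime(cfg)$year
  scenYears <- if (length(spec@scenarioYears)) spec@scenarioYears else
    yrs[yrs >= cfg@startYear + 10L]  # default: last 8 of 18 years
  scenYears <- intersect(scenYears, yrs)
  out <- world

  # deforestation rule
  if (!all(is.na(spec@defTotals))) {
    totals <- rep_len(spec@defTotals, length(scenYears))
    for (i in seq_along(scenYears)) {
      t <- match(scenYears[i], yrs)
      out@deforestation@data[, , t] <-
        scaleDeforestationToTotal(world@deforestation@data[, , t],
                                  totals[i], world@mask)
    }
  } else if (!is.na(spec@defPatternSourceYear)) {
    src <- match(spec@defPatternSourceYear, yrs)
    if (is.na(src)) stop("pattern source year not in the world")
    for (y in scenYears)
      out@deforestation@data[, , match(y, yrs)] <-
        world@deforestation@data[, , src]
  }

  # climate rule
  if (spec@climateMode == "climatology") {
    period <- if (length(spec@climatologyYears)) spec@climatologyYears else yrs
    for (nm in c("precip", "temperature", "lai")) {
      f <- slot(world, nm)
      clim <- climatologicalClimate(f, period)
      g <- slot(out, nm)
      for (y in scenYears) for (m in 1:12) {
        t <- which(f@time$year == y & f@time$month == m)
        g@data[, , t] <- clim@data[, , m]
      }
      slot(out, nm) <- g
    }
  }
  out
}

#' Build a counterfactual scenario feature panel
#'
#' Applies the scenario's deforestation and climate overrides to the world
#' and rebuilds the feature table, so all windowed features (antecedent
#' precipitation, LAI, the 3-year deforestation window) are recomputed after
#' the overrides. Only the overridden drivers differ from the control panel;
#' a control spec reproduces the base panel exactly.
#'
#' @param world a [FireWorld-class].
#' @param fireCounts monthly fire-count [GriddedField-class] (observed; kept
#'   as the target column for bookkeeping).
#' @param spec a [ScenarioSpec-class].
#' @param featureSet passed to [buildFeatureTable()].
#' @return feature table data.frame.
#' @export
buildScenarioPanel <- function(world, fireCounts, spec,
                               featureSet = "clim_lu_def") {
  validObject(spec)
  buildFeatureTable(applyScenarioToWorld(world, spec), fireCounts,
                    featureSet = featureSet)
}

#' Predict scenario fire counts and percent change versus control
#'
#' @param ensemble a trained ensemble (or oracle stub).
#' @param panels named list of feature panels sharing one schema; must
#'   include `"control"`.
#' @return data.frame `scenario`, `year`, `predicted_total`,
#'   `pct_change_vs_control`.
#' @export
predictScenarios <- function(ensemble, panels) {
  if (!"control" %in% names(panels))
    stop("panels must include a 'control' element")
  ctrl <- panels$control
  ctrlTotals <- tapply(predict(ensemble, ctrl), ctrl$year, sum)
  out <- lapply(names(panels), function(nm) {
    p <- panels[[nm]]
    totals <- tapply(predict(ensemble, p), p$year, sum)
    if (!identical(names(totals), names(ctrlTotals)))
      stop("alignment error: scenario years differ from control")
    data.frame(scenario = nm, year = as.integer(names(totals)),
               predicted_total = as.numeric(totals),
               pct_change_vs_control =
                 100 * (as.numeric(totals) - as.numeric(ctrlTotals)) /
                 as.numeric(ctrlTotals))
  })
  do.call(rbind, out)
}

#' Scale fire emissions by predicted fire-count ratios
#'
#' Per cell and month, scaled emissions are
#' `(mlScenario / mlControl) * finnControl` wherever the control prediction
#' is at least `epsilon`; below the floor the ratio is undefined and
#' emissions pass through unchanged (with a warning when any such cell holds
#' non-zero emissions), so emission reductions are never invented where the
#' model has no signal.
#'
#' @param mlControl,mlScenario monthly predicted fire-count
#'   [GriddedField-class]s.
#' @param finnControl monthly emission [GriddedField-class] aligned with
#'   them.
#' @param epsilon zero-control floor in counts (default 0.01).
#' @return emission [GriddedField-class] under the scenario.
#' @export
scaleEmissions <- function(mlControl, mlScenario, finnControl,
                           epsilon = 0.01) {
  stopIfMisaligned(mlControl, mlScenario, "prediction grids")
  stopIfMisaligned(mlControl, finnControl, "prediction and emission grids")
  ratio <- array(1, dim(mlControl@data))
  ok <- mlControl@data >= epsilon
  ratio[ok] <- mlScenario@data[ok] / mlControl@data[ok]
  passthrough <- !ok & finnControl@data > 0
  if (any(passthrough))
    warning(sum(passthrough), " cell-month(s) below the control floor; ",
            "emissions passed through unchanged")
  GriddedField(ratio * finnControl@data, finnControl@lat, finnControl@lon,
               finnControl@time, finnControl@units, "fire_emissions_scaled")
}

#' Percent change between two values
#'
#' @param a reference value (non-zero).
#' @param b comparison value.
#' @param round if `TRUE`, round to the nearest integer for reporting.
#' @return `100 * (b - a) / a`.
#' @examples
#' percentChange(27772, 4571, round = TRUE)  # -84 (an 84% reduction)
#' @export
percentChange <- function(a, b, round = FALSE) {
  if (any(a == 0)) stop("reference value must be non-zero")
  pc <- 100 * (b - a) / a
  if (round) round(pc) else pc
}
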