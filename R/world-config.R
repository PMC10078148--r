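#' Ground-truth fire-rate parameters
#'
#' Parameters of the multiplicative fire-rate model used to generate synthetic
#' fire counts, and the oracle against which trained models are checked. The
#' expected count per cell and month is
#' \deqn{\mu = \beta_0 \, s_m \, e^{\gamma_T (T - T_{ref})}
#'   (P/P_{ref})^{-\gamma_P} (D/D_{ref})^{\gamma_D} (1 + \gamma_L \cdot pasture)}
#' so that \eqn{\gamma_D} is exactly the elasticity of fire count with respect
#' to deforestation, \eqn{\gamma_P} the (negative) elasticity with respect to
#' precipitation, and \eqn{e^{0.1\gamma_T}-1} the fractional increase per
#' +0.1 K. Defaults encode a 0.44 deforestation elasticity, a 0.8
#' precipitation elasticity and a 3.5% increase per +0.1 K.
#'
#' @slot beta0 base rate (counts per cell per month) at the reference point.
#' @slot seasonal 12 multiplicative month factors; the default is flat so all
#'   seasonality is carried by the climate drivers themselves.
#' @slot gammaT temperature coefficient per K.
#' @slot gammaP precipitation elasticity (dimensionless, applied negatively).
#' @slot gammaD deforestation elasticity (dimensionless).
#' @slot gammaL pasture coefficient (dimensionless).
#' @slot tRef reference temperature (degrees C).
#' @slot pRef reference monthly precipitation (mm).
#' @slot dRef reference 3-year deforestation (km2).
#' @slot dFloor floor (km2) substituted for smaller deforestation values so
#'   the rate stays defined on undeforested cells.
#' @export
setClass("FireRateParams",
  representation(beta0 = "numeric", seasonal = "numeric", gammaT = "numeric",
                 gammaP = "numeric", gammaD = "numeric", gammaL = "numeric",
                 tRef = "numeric", pRef = "numeric", dRef = "numeric",
                 dFloor = "numeric"),
  prototype(beta0 = 2, seasonal = rep(1, 12), gammaT = log(1.035) / 0.1,
            gammaP = 0.8, gammaD = 0.44, gammaL = 0.5,
            tRef = 31, pRef = 100, dRef = 10, dFloor = 0.01)
)

setValidity("FireRateParams", function(object) {
  msgs <- character()
  if (object@beta0 <= 0) msgs <- c(msgs, "beta0 must be > 0")
  if (length(object@seasonal) != 12L || any(object@seasonal <= 0))
    msgs <- c(msgs, "seasonal must be 12 positive multipliers")
  if (object@pRef <= 0 || object@dRef <= 0 || object@dFloor <= 0)
    msgs <- c(msgs, "pRef, dRef and dFloor must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname FireRateParams-class
#' @param ... slot overrides, e.g. `gammaD = 0.3`.
#' @return A `FireRateParams` object.
#' @export
fireRateParams <- function(...) new("FireRateParams", ...)

#' Configuration of the synthetic study world
#'
#' Describes the grid, the climate and deforestation generators, the fire,
#' emission and particulate-matter processes, and the demographic inputs.
#' Defaults describe a desk-scale Amazon-biome analogue: a 20 x 30 cell grid
#' at 0.25 degrees, 18 years (2003-2020), drought years mirroring 2005, 2007,
#' 2010 and 2015, and a U-shaped annual deforestation trajectory (decline to a
#' 2012 minimum, then rise) with a persistent spatial frontier.
#'
#' @slot nLat,nLon grid size in cells.
#' @slot lat0,lon0 south-west cell-centre coordinates (degrees).
#' @slot resolution cell size in degrees.
#' @slot nYears number of simulated years (>= 3).
#' @slot startYear calendar year of the first simulated year.
#' @slot seed integer seed; every generator is deterministic given it.
#' @slot droughtYears indices (1-based) of drought years.
#' @slot precipMean,precipAmplitude mean and seasonal amplitude of monthly
#'   precipitation (mm); the wet-season peak is in March.
#' @slot precipNoiseSd lognormal sd of multiplicative monthly precip noise.
#' @slot droughtPrecipFactor multiplicative dry-season (Jun-Oct) precipitation
#'   factor in drought years.
#' @slot droughtTempOffset additive dry-season temperature offset (K) in
#'   drought years.
#' @slot tempMean,tempSeasonalAmplitude daytime land-surface temperature mean
#'   and seasonal amplitude (degrees C); warm peak in the dry season.
#' @slot tempTrend linear interannual warming trend (K per year).
#' @slot tempNoiseSd sd of additive monthly temperature noise (K).
#' @slot laiMean,laiAmplitude,laiNoiseSd leaf-area-index generator parameters.
#' @slot defTrajectory annual biome-wide deforestation totals (km2 per year),
#'   length `nYears`.
#' @slot frontierSmoothness spatial smoothing length (cells) of the
#'   deforestation frontier pattern.
#' @slot frontierJitterSd lognormal sd of the year-to-year jitter applied to
#'   the frontier pattern.
#' @slot fireParams a [FireRateParams-class] object.
#' @slot nbDispersion negative-binomial dispersion k (> 0; variance is
#'   mu + mu^2/k).
#' @slot lowConfidenceFraction fraction of non-persistent detections drawn
#'   with confidence below 66.
#' @slot nPersistentSources number of persistent non-vegetation fire source
#'   cells (gas-flare analogues) emitting every month.
#' @slot persistentMonthlyCount detections per persistent source per month.
#' @slot emissionFactor emitted mass per fire count (kg per count).
#' @slot kernelWidth Gaussian dispersion-kernel sd (cells) of the toy
#'   particulate-matter smoother.
#' @slot pmBackground background PM2.5 (ug/m3).
#' @slot pmPerEmission PM2.5 excess per unit emitted mass (ug/m3 per kg).
#' @slot populationTotal total population of the domain (persons).
#' @slot ageFractions named fractions per age bracket, summing to 1.
#' @slot regionSplit named fractions of population per region, summing to 1;
#'   regions tile the grid as west-to-east slabs.
#' @export
setClass("WorldConfig",
  representation(
    nLat = "integer", nLon = "integer", lat0 = "numeric", lon0 = "numeric",
    resolution = "numeric", nYears = "integer", startYear = "integer",
    seed = "integer", droughtYears = "integer",
    precipMean = "numeric", precipAmplitude = "numeric",
    precipNoiseSd = "numeric", droughtPrecipFactor = "numeric",
    droughtTempOffset = "numeric",
    tempMean = "numeric", tempSeasonalAmplitude = "numeric",
    tempTrend = "numeric", tempNoiseSd = "numeric",
    laiMean = "numeric", laiAmplitude = "numeric", laiNoiseSd = "numeric",
    defTrajectory = "numeric", frontierSmoothness = "numeric",
    frontierJitterSd = "numeric",
    fireParams = "FireRateParams", nbDispersion = "numeric",
    lowConfidenceFraction = "numeric", nPersistentSources = "integer",
    persistentMonthlyCount = "integer",
    emissionFactor = "numeric", kernelWidth = "numeric",
    pmBackground = "numeric", pmPerEmission = "numeric",
    populationTotal = "numeric", ageFractions = "numeric",
    regionSplit = "numeric"
  ),
  prototype(
    nLat = 20L, nLon = 30L, lat0 = -12, lon0 = -70, resolution = 0.25,
    nYears = 18L, startYear = 2003L, seed = 1L,
    droughtYears = c(3L, 5L, 8L, 13L),
    precipMean = 180, precipAmplitude = 140, precipNoiseSd = 0.2,
    droughtPrecipFactor = 0.7, droughtTempOffset = 0.5,
    tempMean = 31, tempSeasonalAmplitude = 1.5, tempTrend = 0.03,
    tempNoiseSd = 0.5,
    laiMean = 4.5, laiAmplitude = 0.8, laiNoiseSd = 0.3,
    defTrajectory = c(25396, 27772, 19014, 14286, 11651, 12911, 7464, 7000,
                      6418, 4571, 5891, 5012, 6207, 7893, 6947, 7536, 10129,
                      10851),
    frontierSmoothness = 3, frontierJitterSd = 0.4,
    fireParams = new("FireRateParams"), nbDispersion = 5,
    lowConfidenceFraction = 0.2, nPersistentSources = 4L,
    persistentMonthlyCount = 2L,
    emissionFactor = 1000, kernelWidth = 1.5, pmBackground = 5,
    pmPerEmission = 2e-5,
    populationTotal = 5e6,
    ageFractions = c("0-24" = 0.40, "25-44" = 0.30, "45-64" = 0.20,
                     "65-79" = 0.08, "80+" = 0.02),
    regionSplit = c(west = 0.6, east = 0.4)
  )
)

setValidity("WorldConfig", function(object) {
  msgs <- character()
  if (object@nLat < 1L || object@nLon < 1L)
    msgs <- c(msgs, "configuration error: grid dimensions must be positive")
  if (object@nYears < 3L)
    msgs <- c(msgs, paste("configuration error: nYears must be >= 3",
                          "(cumulative deforestation window infeasible)"))
  if (object@resolution <= 0)
    msgs <- c(msgs, "configuration error: resolution must be > 0")
  if (length(object@defTrajectory) != object@nYears)
    msgs <- c(msgs, "configuration error: defTrajectory length must equal nYears")
  if (any(object@defTrajectory < 0))
    msgs <- c(msgs, "configuration error: defTrajectory must be non-negative")
  pos <- c(precipMean = object@precipMean, nbDispersion = object@nbDispersion,
           emissionFactor = object@emissionFactor,
           kernelWidth = object@kernelWidth,
           pmPerEmission = object@pmPerEmission,
           populationTotal = object@populationTotal)
  if (any(pos <= 0))
    msgs <- c(msgs, paste("configuration error: strictly positive required:",
                          paste(names(pos)[pos <= 0], collapse = ", ")))
  if (abs(sum(object@ageFractions) - 1) > 1e-9)
    msgs <- c(msgs, "configuration error: ageFractions must sum to 1")
  if (abs(sum(object@regionSplit) - 1) > 1e-9)
    msgs <- c(msgs, "configuration error: regionSplit must sum to 1")
  if (any(object@droughtYears < 1L | object@droughtYears > object@nYears))
    msgs <- c(msgs, "configuration error: droughtYears out of range")
  if (object@lowConfidenceFraction < 0 || object@lowConfidenceFraction > 1)
    msgs <- c(msgs, "configuration error: lowConfidenceFraction in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname WorldConfig-class
#' @param ... slot overrides; `defTrajectory` must match `nYears` if either
#'   is given (a trajectory of the right length is required).
#' @return A `WorldConfig` object.
#' @examples
#' cfg <- worldConfig(nLat = 6L, nLon = 8L, nYears = 5L,
#'                    defTrajectory = c(100, 80, 40, 60, 90))
#' @export
worldConfig <- function(...) {
  args <- list(...)
  # allow plain numerics where integers are stored
  intSlots <- c("nLat", "nLon", "nYears", "startYear", "seed", "droughtYears",
                "nPersistentSources", "persistentMonthlyCount")
  for (s in intSlots) if (s %in% names(args)) args[[s]] <- as.integer(args[[s]])
  if ("nYears" %in% names(args) && !("defTrajectory" %in% names(args))) {
    # rescale the default trajectory shape to the requested length
    def <- new("WorldConfig")@defTrajectory
    n <- args$nYears
    idx <- seq(1, length(def), length.out = max(n, 1L))
    args$defTrajectory <- stats::approx(seq_along(def), def, idx)$y
  }
  if ("droughtYears" %in% names(args) || !("nYears" %in% names(args))) {
    # keep user/default value
  } else {
    d <- new("WorldConfig")@droughtYears
    args$droughtYears <- d[d <= args$nYears]
  }
  do.call(new, c(list("WorldConfig"), args))
}

#' Cell-centre coordinates of a world configuration
#' @param config a [WorldConfig-class].
#' @return list with numeric vectors `lat` and `lon`.
#' @export
gridCoords <- function(config) {
  list(lat = config@lat0 + (seq_len(config@nLat) - 1L) * config@resolution,
       lon = config@lon0 + (seq_len(config@nLon) - 1L) * config@resolution)
}
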