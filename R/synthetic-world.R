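#' Synthetic study world
#'
#' Bundle of gridded inputs produced by [generateWorld()]: monthly
#' precipitation, temperature and leaf area index, annual deforestation,
#' static land-cover fractions and the biome mask, together with the
#' configuration that generated them.
#'
#' @slot precip,temperature,lai monthly [GriddedField-class]s.
#' @slot deforestation annual [GriddedField-class] (km2 per cell per year).
#' @slot landCover list of matrices `pasture`, `cropland`, `savannah` with
#'   fractions in `[0, 1]`.
#' @slot mask logical matrix of biome cells.
#' @slot config the generating [WorldConfig-class].
#' @export
setClass("FireWorld",
  representation(precip = "GriddedField", temperature = "GriddedField",
                 lai = "GriddedField", deforestation = "GriddedField",
                 landCover = "list", mask = "matrix", config = "WorldConfig"))

setMethod("show", "FireWorld", function(object) {
  cfg <- object@config
  cat("FireWorld: ", cfg@nLat, " x ", cfg@nLon, " cells (",
      sum(object@mask), " in biome), years ", cfg@startYear, "-",
      cfg@startYear + cfg@nYears - 1L, "\n", sep = "")
  cat("  annual deforestation totals (km2): ",
      paste(round(cfg@defTrajectory), collapse = " "), "\n", sep = "")
})

#' @describeIn FireWorld biome mask accessor
#' @param x a `FireWorld`
#' @export
worldMask <- function(x) x@mask

#' @describeIn FireWorld configuration accessor
#' @export
worldConfigOf <- function(x) x@config

monthTime <- function(config) {
  data.frame(year = rep(config@startYear + seq_len(config@nYears) - 1L,
                        each = 12L),
             month = rep(1:12, config@nYears))
}

annualTime <- function(config) {
  data.frame(year = config@startYear + seq_len(config@nYears) - 1L,
             month = NA_integer_)
}

#' Generate the synthetic gridded world
#'
#' Produces all gridded inputs of the pipeline with known statistical
#' structure: seasonal precipitation with drought years (dry-season deficit),
#' seasonally varying and slowly warming surface temperature, leaf area index,
#' an annual deforestation field with a persistent spatial frontier whose
#' masked totals match the configured trajectory exactly, static land-cover
#' fractions correlated with the frontier, and an elliptical biome mask.
#' Deterministic given `config@seed`.
#'
#' @param config a [WorldConfig-class].
#' @return A [FireWorld-class] object.
#' @examples
#' w <- generateWorld(worldConfig(nLat = 6L, nLon = 8L, nYears = 4L,
#'                                defTrajectory = c(100, 50, 80, 120)))
#' annualTotals(w@deforestation, worldMask(w))
#' @export
generateWorld <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nr <- config@nLat; nc <- config@nLon
  ny <- config@nYears; nm <- 12L * ny
  co <- gridCoords(config)

  # biome mask: ellipse in index space, wobbled by smoothed noise
  ri <- (row(matrix(0, nr, nc)) - (nr + 1) / 2) / (0.55 * nr)
  ci <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) / (0.55 * nc)
  wob <- smoothMatrix(matrix(stats::rnorm(nr * nc), nr, nc), 2)
  mask <- (ri^2 + ci^2 + 0.15 * wob) < 1

  # static spatial modifiers
  precipSpatial <- exp(smoothMatrix(matrix(stats::rnorm(nr * nc, 0, 0.5),
                                           nr, nc), config@frontierSmoothness))
  precipSpatial <- precipSpatial / mean(precipSpatial)
  tempSpatial <- smoothMatrix(matrix(stats::rnorm(nr * nc, 0, 1), nr, nc), 3)
  laiSpatial <- smoothMatrix(matrix(stats::rnorm(nr * nc, 0, 0.8), nr, nc), 3)

  drought <- seq_len(ny) %in% config@droughtYears
  dryMonths <- 6:10

  precip <- array(0, c(nr, nc, nm))
  temp <- array(0, c(nr, nc, nm))
  lai <- array(0, c(nr, nc, nm))
  for (y in seq_len(ny)) {
    for (m in 1:12) {
      t <- (y - 1L) * 12L + m
      pSeason <- config@precipMean +
        config@precipAmplitude * cos(2 * pi * (m - 3) / 12)
      p <- pSeason * precipSpatial *
        exp(stats::rnorm(nr * nc, 0, config@precipNoiseSd))
      if (drought[y] && m %in% dryMonths) p <- p * config@droughtPrecipFactor
      precip[, , t] <- pmax(p, 1)

      tv <- config@tempMean +
        config@tempSeasonalAmplitude * cos(2 * pi * (m - 9) / 12) +
        config@tempTrend * (y - 1L) + tempSpatial +
        stats::rnorm(nr * nc, 0, config@tempNoiseSd)
      if (drought[y] && m %in% dryMonths) tv <- tv + config@droughtTempOffset
      temp[, , t] <- tv

      lv <- config@laiMean +
        config@laiAmplitude * cos(2 * pi * (m - 3) / 12) * 0.5 + laiSpatial +
        stats::rnorm(nr * nc, 0, config@laiNoiseSd)
      lai[, , t] <- pmax(lv, 0.1)
    }
  }

  # deforestation frontier: persistent south-east gradient + smooth noise,
  # jittered per year, renormalised so masked totals match the trajectory
  rowFrac <- (row(matrix(0, nr, nc)) - 1) / max(nr - 1, 1)
  colFrac <- (col(matrix(0, nr, nc)) - 1) / max(nc - 1, 1)
  frontier <- exp(2.5 * (0.6 * colFrac + 0.4 * (1 - rowFrac)) +
                  1.2 * smoothMatrix(matrix(stats::rnorm(nr * nc), nr, nc),
                                     config@frontierSmoothness))
  defo <- array(0, c(nr, nc, ny))
  for (y in seq_len(ny)) {
    wy <- frontier * exp(stats::rnorm(nr * nc, 0, config@frontierJitterSd))
    wy[!mask] <- 0
    tot <- sum(wy)
    defo[, , y] <- if (tot > 0) wy / tot * config@defTrajectory[y] else wy
  }

  # static land cover tied to the long-run frontier
  f01 <- frontier / max(frontier)
  pasture <- pmin(0.7, pmax(0, 0.6 * f01 +
                              0.05 * matrix(stats::rnorm(nr * nc), nr, nc)))
  cropland <- pmin(0.3, pmax(0, 0.25 * f01 +
                               0.04 * matrix(stats::rnorm(nr * nc), nr, nc)))
  savannah <- pmin(0.4, pmax(0, 0.25 * (1 - f01) +
                               0.05 * matrix(stats::rnorm(nr * nc), nr, nc)))
  over <- pasture + cropland + savannah
  fix <- over > 1
  if (any(fix)) {
    pasture[fix] <- pasture[fix] / over[fix]
    cropland[fix] <- cropland[fix] / over[fix]
    savannah[fix] <- savannah[fix] / over[fix]
  }
  pasture[!mask] <- 0; cropland[!mask] <- 0; savannah[!mask] <- 0

  mt <- monthTime(config); at <- annualTime(config)
  new("FireWorld",
      precip = GriddedField(precip, co$lat, co$lon, mt, "mm", "precipitation"),
      temperature = GriddedField(temp, co$lat, co$lon, mt, "degC",
                                 "surface_temperature"),
      lai = GriddedField(lai, co$lat, co$lon, mt, "m2/m2", "lai"),
      deforestation = GriddedField(defo, co$lat, co$lon, at, "km2",
                                   "deforestation"),
      landCover = list(pasture = pasture, cropland = cropland,
                       savannah = savannah),
      mask = mask, config = config)
}

#' Expected fire rate (generative oracle)
#'
#' Evaluates the ground-truth multiplicative rate model
#' \eqn{\mu = \beta_0 s_m e^{\gamma_T (T-T_{ref})} (P/P_{ref})^{-\gamma_P}
#' (\max(D, D_{floor})/D_{ref})^{\gamma_D} (1+\gamma_L \cdot pasture)}.
#' All arguments are vectorised.
#'
#' @param temperature surface temperature (degrees C).
#' @param precip monthly precipitation (mm), strictly positive.
#' @param deforestation 3-year cumulative deforestation (km2), >= 0; values
#'   below `params@dFloor` are floored so the rate stays defined.
#' @param pasture pasture fraction in `[0, 1]`.
#' @param month month 1-12 (selects the seasonal multiplier).
#' @param params a [FireRateParams-class].
#' @return expected counts per cell per month (strictly positive).
#' @examples
#' p <- fireRateParams()
#' expectedFireRate(p@tRef, p@pRef, p@dRef, 0, 1, p)  # = beta0
#' @export
expectedFireRate <- function(temperature, precip, deforestation, pasture,
                             month, params = fireRateParams()) {
  if (!all(is.finite(temperature)) || !all(is.finite(precip)) ||
      !all(is.finite(deforestation)) || !all(is.finite(pasture)))
    stop("computation error: non-finite inputs to expectedFireRate")
  if (any(precip <= 0)) stop("computation error: precip must be > 0")
  if (any(deforestation < 0))
    stop("computation error: deforestation must be >= 0")
  d <- pmax(deforestation, params@dFloor)
  params@beta0 * params@seasonal[month] *
    exp(params@gammaT * (temperature - params@tRef)) *
    (precip / params@pRef)^(-params@gammaP) *
    (d / params@dRef)^params@gammaD *
    (1 + params@gammaL * pasture)
}

# 3-year deforestation window per cell for generator use; pads the first two
# years by reusing the earliest available years.
paddedDefWindow <- function(defo, y) {
  ys <- pmax(c(y - 2L, y - 1L, y), 1L)
  defo[, , ys[1]] + defo[, , ys[2]] + defo[, , ys[3]]
}

# expected-rate array (lat, lon, month-index) for a whole world
expectedRateArray <- function(world, params = world@config@fireParams) {
  cfg <- world@config
  nr <- cfg@nLat; nc <- cfg@nLon; ny <- cfg@nYears
  mu <- array(0, c(nr, nc, 12L * ny))
  for (y in seq_len(ny)) {
    d3 <- paddedDefWindow(world@deforestation@data, y)
    for (m in 1:12) {
      t <- (y - 1L) * 12L + m
      mu[, , t] <- expectedFireRate(world@temperature@data[, , t],
                                    world@precip@data[, , t],
                                    d3, world@landCover$pasture, m, params)
    }
  }
  mu
}

#' Deterministic persistent-source cells of a world
#'
#' The configured number of persistent non-vegetation fire sources (flare
#' analogues), chosen reproducibly from the biome mask by the world seed.
#'
#' @param world a [FireWorld-class].
#' @return data.frame with columns `row`, `col`, `cell` (cell id).
#' @export
persistentSourceCells <- function(world) {
  cfg <- world@config
  idx <- which(world@mask)
  if (length(idx) == 0L || cfg@nPersistentSources == 0L)
    return(data.frame(row = integer(), col = integer(),
                      cell = character()))
  set.seed(cfg@seed + 7777L)
  pick <- sort(sample(idx, min(cfg@nPersistentSources, length(idx))))
  rr <- ((pick - 1L) %% cfg@nLat) + 1L
  cc <- ((pick - 1L) %/% cfg@nLat) + 1L
  data.frame(row = rr, col = cc, cell = sprintf("r%02dc%02d", rr, cc))
}

#' Generate daily fire detections
#'
#' Draws the number of vegetation-fire detections per cell and month from a
#' negative-binomial distribution with mean given by [expectedFireRate()]
#' (using the 3-year deforestation window of each year) and dispersion `k`,
#' then scatters the detections uniformly in space within the cell and in time
#' within the month. Confidence values are drawn from a two-component uniform
#' mixture so that a configured fraction falls below 66. Persistent-source
#' cells additionally emit a fixed number of flagged detections every month.
#'
#' @param world a [FireWorld-class].
#' @param params fire-rate parameters; defaults to the world's.
#' @param dispersion negative-binomial k (> 0); defaults to the world's.
#' @param seed integer seed; defaults to the world seed.
#' @return data.frame with columns `date` (Date), `lon`, `lat`, `confidence`
#'   (percent in `[0, 100]`) and `persistent` (logical).
#' @export
generateFireDetections <- function(world, params = world@config@fireParams,
                                   dispersion = world@config@nbDispersion,
                                   seed = world@config@seed) {
  cfg <- world@config
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("configuration error: dispersion k must be > 0")
  mu <- expectedRateArray(world, params)
  maskv <- as.vector(world@mask)
  set.seed(seed + 1L)
  nr <- cfg@nLat; nc <- cfg@nLon
  co <- gridCoords(cfg)
  res <- cfg@resolution
  west <- co$lon - res / 2; south <- co$lat - res / 2
  ps <- persistentSourceCells(world)
  tm <- monthTime(cfg)

  out <- vector("list", dim(mu)[3])
  for (t in seq_len(dim(mu)[3])) {
    muv <- as.vector(mu[, , t])
    muv[!maskv] <- 0
    n <- stats::rnbinom(length(muv), size = dispersion, mu = muv)
    n[muv == 0] <- 0L
    cells <- rep(seq_along(n), n)
    nPers <- nrow(ps) * cfg@persistentMonthlyCount
    persCells <- rep((ps$col - 1L) * nr + ps$row,
                     each = cfg@persistentMonthlyCount)
    allCells <- c(cells, persCells)
    ntot <- length(allCells)
    if (ntot == 0L) next
    rr <- ((allCells - 1L) %% nr) + 1L
    cc <- ((allCells - 1L) %/% nr) + 1L
    lonPt <- west[cc] + stats::runif(ntot) * res
    latPt <- south[rr] + stats::runif(ntot) * res
    nVeg <- length(cells)
    lowMask <- stats::runif(nVeg) < cfg@lowConfidenceFraction
    confVeg <- ifelse(lowMask, stats::runif(nVeg, 20, 66),
                      stats::runif(nVeg, 66, 100))
    conf <- c(confVeg, stats::runif(ntot - nVeg, 66, 100))
    day <- sample.int(28L, ntot, replace = TRUE)
    date <- as.Date(sprintf("%04d-%02d-%02d", tm$year[t], tm$month[t], day))
    out[[t]] <- data.frame(date = date, lon = lonPt, lat = latPt,
                           confidence = conf,
                           persistent = rep(c(FALSE, TRUE),
                                            c(nVeg, ntot - nVeg)))
  }
  dets <- do.call(rbind, out)
  if (is.null(dets))
    dets <- data.frame(date = as.Date(character()), lon = numeric(),
                       lat = numeric(), confidence = numeric(),
                       persistent = logical())
  rownames(dets) <- NULL
  dets
}

# truncated (not renormalised) Gaussian convolution; mass within the grid is
# preserved for interior sources
convolve2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(w, w); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (di in -r:r) {
    if (min(nr, nr - di) < max(1, 1 - di)) next
    si <- max(1, 1 - di):min(nr, nr - di)
    ti <- si + di
    for (dj in -r:r) {
      if (min(nc, nc - dj) < max(1, 1 - dj)) next
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      tj <- sj + dj
      acc[ti, tj] <- acc[ti, tj] + k[di + r + 1, dj + r + 1] * m[si, sj]
    }
  }
  acc
}

#' Emissions proportional to fire counts
#'
#' @param counts monthly fire-count [GriddedField-class].
#' @param emissionFactor mass per count (kg per count).
#' @return monthly emission [GriddedField-class] (kg per month).
#' @export
emissionsFromCounts <- function(counts, emissionFactor) {
  if (emissionFactor <= 0) stop("configuration error: emissionFactor must be > 0")
  GriddedField(counts@data * emissionFactor, counts@lat, counts@lon,
               counts@time, "kg", "fire_emissions")
}

#' Toy annual-mean PM2.5 fields from monthly emissions
#'
#' A declared stand-in for a chemistry-transport simulation, used only so the
#' health module has spatially coherent exposure fields: annual emissions are
#' summed per year, convolved with a fixed truncated Gaussian kernel and
#' scaled linearly, on top of a uniform background. Exactly linear in
#' emissions above background; it does not emulate atmospheric chemistry or
#' meteorology.
#'
#' @param emissions monthly emission [GriddedField-class] (kg/month), >= 0.
#' @param config a [WorldConfig-class] supplying `kernelWidth`,
#'   `pmBackground` and `pmPerEmission`.
#' @return annual [GriddedField-class] of PM2.5 (ug/m3).
#' @export
generatePmField <- function(emissions, config) {
  if (any(emissions@data < 0))
    stop("input error: emissions must be non-negative")
  yrs <- sort(unique(emissions@time$year))
  nr <- length(emissions@lat); nc <- length(emissions@lon)
  pm <- array(0, c(nr, nc, length(yrs)))
  for (i in seq_along(yrs)) {
    idx <- which(emissions@time$year == yrs[i])
    annual <- matrix(0, nr, nc)
    for (t in idx) annual <- annual + emissions@data[, , t]
    pm[, , i] <- config@pmBackground +
      config@pmPerEmission * convolve2d(annual, config@kernelWidth)
  }
  GriddedField(pm, emissions@lat, emissions@lon,
               data.frame(year = yrs, month = NA_integer_), "ug/m3",
               "pm25_annual")
}

#' Generate gridded population, age structure, baseline rates and regions
#'
#' Population is a smooth lognormal field split into west-to-east regional
#' slabs whose totals match `config@regionSplit` of `config@populationTotal`
#' exactly. Baseline mortality/YLL/YLD rates rise with age and differ mildly
#' between regions; all values are synthetic conventions.
#'
#' @param config a [WorldConfig-class].
#' @param seed integer seed (defaults to the config seed).
#' @return list with elements `population` (static [GriddedField-class]),
#'   `ageFractions` (named vector summing to 1), `baselineRates` (data.frame
#'   `region`, `outcome`, `age`, `mortality`, `yll`, `yld`, events per person
#'   per year), `regionField` (integer matrix of region ids), and `regions`
#'   (data.frame `region`, `id`, with slab column ranges).
#' @export
generatePopulation <- function(config, seed = config@seed) {
  set.seed(seed + 2L)
  nr <- config@nLat; nc <- config@nLon
  co <- gridCoords(config)
  raw <- exp(smoothMatrix(matrix(stats::rnorm(nr * nc, 0, 1), nr, nc), 2))
  regions <- names(config@regionSplit)
  nReg <- length(regions)
  if (nReg < 1L) stop("configuration error: at least one region required")
  # split columns proportionally to the population share
  edges <- round(cumsum(config@regionSplit) * nc)
  edges[nReg] <- nc
  starts <- c(1L, utils::head(edges, -1L) + 1L)
  regionField <- matrix(0L, nr, nc)
  pop <- matrix(0, nr, nc)
  for (i in seq_len(nReg)) {
    cols <- starts[i]:edges[i]
    regionField[, cols] <- i
    block <- raw[, cols, drop = FALSE]
    pop[, cols] <- block / sum(block) *
      config@regionSplit[i] * config@populationTotal
  }
  ages <- names(config@ageFractions)
  adult <- ages[ages != "0-24"]
  mort <- c("25-44" = 0.002, "45-64" = 0.008, "65-79" = 0.030, "80+" = 0.100)
  yllF <- c("25-44" = 35, "45-64" = 20, "65-79" = 10, "80+" = 4)
  rates <- do.call(rbind, lapply(seq_len(nReg), function(i) {
    mult <- 1 + 0.1 * (i - 1)
    data.frame(region = regions[i], outcome = "ncd_lri", age = adult,
               mortality = unname(mort[adult]) * mult,
               yll = unname(mort[adult] * yllF[adult]) * mult,
               yld = unname(mort[adult] * yllF[adult]) * 0.3 * mult)
  }))
  list(population = GriddedField(pop, co$lat, co$lon, units = "persons",
                                 name = "population"),
       ageFractions = config@ageFractions,
       baselineRates = rates,
       regionField = regionField,
       regions = data.frame(region = regions, id = seq_len(nReg),
                            colStart = starts, colEnd = edges))
}
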