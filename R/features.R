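#' Cell ids for point locations
#'
#' Assigns points to grid cells with the half-open convention
#' `[west, east) x [south, north)`: a point lying exactly on a cell's west or
#' south edge belongs to that cell.
#'
#' @param lon,lat point coordinates (degrees).
#' @param config a [WorldConfig-class] describing the grid.
#' @return character vector of cell ids (`"r<row>c<col>"`).
#' @export
cellIds <- function(lon, lat, config) {
  res <- config@resolution
  cc <- floor((lon - (config@lon0 - res / 2)) / res) + 1L
  rr <- floor((lat - (config@lat0 - res / 2)) / res) + 1L
  bad <- cc < 1L | cc > config@nLon | rr < 1L | rr > config@nLat
  if (any(bad))
    stop("detection outside grid extent (", sum(bad), " point(s))")
  sprintf("r%02dc%02d", rr, cc)
}

checkDetections <- function(detections) {
  need <- c("date", "lon", "lat", "confidence", "persistent")
  miss <- setdiff(need, names(detections))
  if (length(miss))
    stop("parse error: detection table missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(detections$lon) | !is.finite(detections$lat) |
                 !is.finite(detections$confidence) |
                 detections$confidence < 0 | detections$confidence > 100)
  if (length(bad))
    stop("parse error: malformed detection record at row ", bad[1L])
  invisible(TRUE)
}

#' Filter fire detections by confidence and persistent sources
#'
#' Keeps detections with confidence greater than or equal to the threshold
#' (the boundary value is kept), that are not flagged as persistent sources,
#' and whose cell is not in a supplied persistent-source cell set. Row order
#' is preserved.
#'
#' @param detections data.frame as returned by [generateFireDetections()].
#' @param confidenceThreshold percent in `[0, 100]`; default 66.
#' @param persistentCells optional character vector of cell ids to drop
#'   (requires `config` to locate detections).
#' @param config a [WorldConfig-class]; needed only with `persistentCells`.
#' @return the filtered detection data.frame.
#' @export
filterFireDetections <- function(detections, confidenceThreshold = 66,
                                 persistentCells = character(0),
                                 config = NULL) {
  if (confidenceThreshold < 0 || confidenceThreshold > 100)
    stop("confidenceThreshold must be in [0, 100]")
  checkDetections(detections)
  keep <- detections$confidence >= confidenceThreshold &
    !detections$persistent
  if (length(persistentCells)) {
    if (is.null(config))
      stop("config required to resolve persistentCells")
    keep <- keep & !(cellIds(detections$lon, detections$lat, config) %in%
                       persistentCells)
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid detections to monthly fire counts
#'
#' Sums detections per cell and calendar month over the world's full time
#' axis, assigning each detection to exactly one cell under the half-open
#' cell convention. The grid total of a month equals the number of
#' detections in that month.
#'
#' @param detections (filtered) detection data.frame.
#' @param world a [FireWorld-class] supplying grid geometry and time axis.
#' @return monthly [GriddedField-class] of counts.
#' @export
gridMonthlyFireCounts <- function(detections, world) {
  cfg <- world@config
  checkDetections(detections)
  nr <- cfg@nLat; nc <- cfg@nLon
  tm <- monthTime(cfg)
  counts <- array(0, c(nr, nc, nrow(tm)))
  if (nrow(detections)) {
    res <- cfg@resolution
    cc <- floor((detections$lon - (cfg@lon0 - res / 2)) / res) + 1L
    rr <- floor((detections$lat - (cfg@lat0 - res / 2)) / res) + 1L
    bad <- cc < 1L | cc > nc | rr < 1L | rr > nr
    if (any(bad)) stop("detection outside grid extent")
    dyear <- as.integer(format(detections$date, "%Y"))
    dmonth <- as.integer(format(detections$date, "%m"))
    t <- match(paste(dyear, dmonth), paste(tm$year, tm$month))
    if (anyNA(t)) stop("detection outside world time range")
    idx <- (t - 1L) * nr * nc + (cc - 1L) * nr + rr
    tab <- tabulate(idx, nbins = length(counts))
    counts <- array(tab, dim(counts))
  }
  co <- gridCoords(cfg)
  GriddedField(counts, co$lat, co$lon, tm, "count", "fire_count")
}

#' 3-year cumulative deforestation for a reference year
#'
#' Per cell, the deforested area in the reference year plus the two preceding
#' years. The reference year must have two predecessors in the field.
#'
#' @param deforestation annual [GriddedField-class].
#' @param referenceYear calendar year.
#' @return matrix `(lat, lon)` in km2.
#' @export
cumulativeDeforestation <- function(deforestation, referenceYear) {
  yrs <- deforestation@time$year
  need <- (referenceYear - 2L):referenceYear
  if (!all(need %in% yrs))
    stop("reference year ", referenceYear,
         " lacks two predecessor years in the deforestation field")
  i <- match(need, yrs)
  deforestation@data[, , i[1]] + deforestation@data[, , i[2]] +
    deforestation@data[, , i[3]]
}

#' Antecedent precipitation: total over the preceding 6 months
#'
#' The current month is excluded ("preceding" is read literally), which also
#' prevents same-month rainfall from leaking into its own antecedent sum.
#'
#' @param precip monthly [GriddedField-class].
#' @param row,col cell indices.
#' @param year,month reference time; the 6 prior months must exist.
#' @param includeCurrent if `TRUE`, sums months t-5..t instead (config
#'   switch; default `FALSE`).
#' @return total precipitation (mm).
#' @export
antecedentPrecip <- function(precip, row, col, year, month,
                             includeCurrent = FALSE) {
  t <- match(paste(year, month),
             paste(precip@time$year, precip@time$month))
  if (is.na(t)) stop("reference month not on the precip time axis")
  win <- if (includeCurrent) (t - 5L):t else (t - 6L):(t - 1L)
  if (win[1L] < 1L) stop("fewer than 6 prior months available")
  sum(precip@data[row, col, win])
}

#' Antecedent LAI: mean over the preceding 12 months
#'
#' @param lai monthly [GriddedField-class].
#' @param row,col cell indices.
#' @param year,month reference time; the 12 prior months must exist.
#' @return mean LAI (area/area).
#' @export
antecedentLai <- function(lai, row, col, year, month) {
  t <- match(paste(year, month), paste(lai@time$year, lai@time$month))
  if (is.na(t)) stop("reference month not on the LAI time axis")
  win <- (t - 12L):(t - 1L)
  if (win[1L] < 1L) stop("fewer than 12 prior months available")
  mean(lai@data[row, col, win])
}

featureSetColumns <- function(featureSet) {
  clim <- c("precip", "precip_prev6", "temperature", "lai_prev12")
  lu <- c("pasture_frac", "cropland_frac", "savannah_frac")
  def <- "deforestation_3yr"
  switch(featureSet,
         clim = clim,
         clim_lu = c(clim, lu),
         clim_def = c(clim, def),
         clim_lu_def = c(clim, lu, def),
         stop("unknown featureSet: ", featureSet))
}

#' Build the monthly cell-level feature panel
#'
#' Vectorises the gridded inputs into one row per masked cell and usable
#' month. Usable months are those of the third simulated year onward, so that
#' the 6-month precipitation window, the 12-month LAI window and the 3-year
#' deforestation window are all defined; earlier rows are dropped rather than
#' padded. The feature set selects columns: `"clim"` (precipitation,
#' antecedent precipitation, temperature, antecedent LAI), `"clim_lu"`
#' (adding pasture/cropland/savannah percent fractions), `"clim_def"`
#' (adding the 3-year deforestation window) or `"clim_lu_def"` (all).
#'
#' @param world a [FireWorld-class].
#' @param fireCounts monthly fire-count [GriddedField-class] aligned with the
#'   world (e.g. from [gridMonthlyFireCounts()]).
#' @param featureSet one of `"clim"`, `"clim_lu"`, `"clim_def"`,
#'   `"clim_lu_def"`.
#' @param includeCurrentPrecip passed to the antecedent-precipitation window.
#' @return data.frame with id columns `cell`, `lon`, `lat`, `year`, `month`,
#'   target `fire_count`, and the selected feature columns.
#' @export
buildFeatureTable <- function(world, fireCounts,
                              featureSet = "clim_lu_def",
                              includeCurrentPrecip = FALSE) {
  cfg <- world@config
  stopIfMisaligned(world@precip, fireCounts, "world and fire counts")
  cols <- featureSetColumns(featureSet)
  nr <- cfg@nLat; nc <- cfg@nLon
  maskIdx <- which(world@mask)
  nCell <- length(maskIdx)
  if (nCell == 0L) {
    empty <- data.frame(cell = character(), lon = numeric(), lat = numeric(),
                        year = integer(), month = integer(),
                        fire_count = numeric(), precip = numeric(),
                        precip_prev6 = numeric(), temperature = numeric(),
                        lai_prev12 = numeric(), pasture_frac = numeric(),
                        cropland_frac = numeric(), savannah_frac = numeric(),
                        deforestation_3yr = numeric())
    return(empty[, c("cell", "lon", "lat", "year", "month", "fire_count",
                     cols)])
  }
  rr <- ((maskIdx - 1L) %% nr) + 1L
  cc <- ((maskIdx - 1L) %/% nr) + 1L
  co <- gridCoords(cfg)
  cellId <- sprintf("r%02dc%02d", rr, cc)

  nm <- 12L * cfg@nYears
  flat <- function(a) matrix(a, nr * nc, nm)[maskIdx, , drop = FALSE]
  P <- flat(world@precip@data)
  TT <- flat(world@temperature@data)
  L <- flat(world@lai@data)
  FC <- flat(fireCounts@data)

  # windowed features via cumulative sums along time
  csP <- cbind(0, t(apply(P, 1L, cumsum)))
  csL <- cbind(0, t(apply(L, 1L, cumsum)))
  usable <- (2L * 12L + 1L):nm  # years >= 3
  off <- if (includeCurrentPrecip) 0L else 1L
  prev6 <- csP[, usable + 1L - off] - csP[, usable - 5L - off]
  prev12 <- (csL[, usable] - csL[, usable - 12L]) / 12

  yearsUsable <- cfg@startYear + 2:(cfg@nYears - 1L)
  rows <- vector("list", length(usable))
  lu <- world@landCover
  for (j in seq_along(usable)) {
    t <- usable[j]
    y <- cfg@startYear + (t - 1L) %/% 12L
    m <- (t - 1L) %% 12L + 1L
    d3 <- cumulativeDeforestation(world@deforestation, y)
    df <- data.frame(cell = cellId, lon = co$lon[cc], lat = co$lat[rr],
                     year = y, month = m, fire_count = FC[, t],
                     precip = P[, t], precip_prev6 = prev6[, j],
                     temperature = TT[, t], lai_prev12 = prev12[, j],
                     pasture_frac = 100 * lu$pasture[maskIdx],
                     cropland_frac = 100 * lu$cropland[maskIdx],
                     savannah_frac = 100 * lu$savannah[maskIdx],
                     deforestation_3yr = d3[maskIdx])
    rows[[j]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$month, out$cell), ]
  rownames(out) <- NULL
  out[, c("cell", "lon", "lat", "year", "month", "fire_count", cols)]
}
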