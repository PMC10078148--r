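#' @import methods
NULL

#' GriddedField: a lat/lon(/time) raster
#'
#' The common currency of the pipeline: a regular latitude/longitude raster,
#' optionally with a monthly or annual time axis, carrying units and a name.
#' Data are stored as an array with dimensions `(lat, lon)` for static fields
#' or `(lat, lon, time)` for time-varying fields; latitudes and longitudes are
#' cell-centre coordinates, ascending south-to-north and west-to-east.
#'
#' @slot name character scalar identifying the variable.
#' @slot units character scalar (e.g. `"mm"`, `"degC"`, `"km2"`, `"ug/m3"`).
#' @slot data numeric matrix `(lat, lon)` or array `(lat, lon, time)`.
#' @slot lat numeric vector of cell-centre latitudes (ascending).
#' @slot lon numeric vector of cell-centre longitudes (ascending).
#' @slot time data.frame with integer columns `year` and `month` (one row per
#'   time slice; `month` is `NA` for annual fields). Zero rows for static
#'   fields.
#'
#' @examples
#' f <- GriddedField(matrix(1:6, 2, 3), lat = c(-1.875, -1.625),
#'                   lon = c(-70.875, -70.625, -70.375), units = "mm")
#' gridLat(f)
#' @export
setClass("GriddedField",
  representation(
    name  = "character",
    units = "character",
    data  = "array",
    lat   = "numeric",
    lon   = "numeric",
    time  = "data.frame"
  ),
  prototype(name = "", units = "", time = data.frame(year = integer(),
                                                     month = integer()))
)

setValidity("GriddedField", function(object) {
  d <- dim(object@data)
  msgs <- character()
  if (!(length(d) %in% c(2L, 3L)))
    msgs <- c(msgs, "data must be a 2- or 3-dimensional array")
  if (length(d) >= 2L) {
    if (d[1L] != length(object@lat))
      msgs <- c(msgs, "dim(data)[1] must equal length(lat)")
    if (d[2L] != length(object@lon))
      msgs <- c(msgs, "dim(data)[2] must equal length(lon)")
  }
  nt <- if (length(d) == 3L) d[3L] else 0L
  if (nrow(object@time) != nt)
    msgs <- c(msgs, "nrow(time) must match the third data dimension")
  if (length(object@lat) > 1L && any(diff(object@lat) <= 0))
    msgs <- c(msgs, "lat must be strictly ascending")
  if (length(object@lon) > 1L && any(diff(object@lon) <= 0))
    msgs <- c(msgs, "lon must be strictly ascending")
  if (!all(c("year", "month") %in% names(object@time)))
    msgs <- c(msgs, "time must have columns 'year' and 'month'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GriddedField
#'
#' @param data matrix `(lat, lon)` or array `(lat, lon, time)`.
#' @param lat,lon cell-centre coordinates in degrees, ascending.
#' @param time `NULL` for a static field, or a data.frame with columns
#'   `year` and `month` (use `NA` months for annual fields).
#' @param units units string recorded in the field metadata.
#' @param name variable name.
#' @return A [GriddedField-class] object.
#' @export
GriddedField <- function(data, lat, lon, time = NULL, units = "", name = "") {
  if (is.null(time)) time <- data.frame(year = integer(), month = integer())
  time$year <- as.integer(time$year)
  time$month <- as.integer(time$month)
  if (is.matrix(data) && nrow(time) > 0L)
    data <- array(data, dim = c(dim(data), nrow(time)))
  new("GriddedField", name = as.character(name), units = as.character(units),
      data = as.array(data), lat = as.numeric(lat), lon = as.numeric(lon),
      time = time)
}

#' @describeIn GriddedField data array accessor
#' @param x,object a `GriddedField`
#' @export
gridData <- function(x) x@data

#' @describeIn GriddedField latitude accessor
#' @export
gridLat <- function(x) x@lat

#' @describeIn GriddedField longitude accessor
#' @export
gridLon <- function(x) x@lon

#' @describeIn GriddedField time-axis accessor
#' @export
gridTime <- function(x) x@time

#' @describeIn GriddedField units accessor
#' @export
gridUnits <- function(x) x@units

setMethod("show", "GriddedField", function(object) {
  d <- dim(object@data)
  cat("GriddedField \"", object@name, "\" [", object@units, "]\n", sep = "")
  cat("  grid: ", length(object@lat), " lat x ", length(object@lon),
      " lon", sep = "")
  if (length(d) == 3L) {
    mo <- object@time$month
    kind <- if (all(is.na(mo))) "annual" else "monthly"
    cat(" x ", d[3L], " time (", kind, ", years ",
        min(object@time$year), "-", max(object@time$year), ")", sep = "")
  }
  cat("\n  range: [", format(min(object@data), digits = 4), ", ",
      format(max(object@data), digits = 4), "]\n", sep = "")
})

#' Extract one time slice of a GriddedField as a matrix
#'
#' @param field a [GriddedField-class] with a time axis.
#' @param year integer year.
#' @param month integer month 1-12, or `NULL` for annual fields.
#' @return numeric matrix `(lat, lon)`.
#' @export
fieldSlice <- function(field, year, month = NULL) {
  tm <- field@time
  i <- if (is.null(month)) which(tm$year == year & is.na(tm$month))
       else which(tm$year == year & tm$month == month)
  if (length(i) != 1L)
    stop("no unique time slice for year ", year,
         if (!is.null(month)) paste0(", month ", month))
  field@data[, , i]
}

#' Check that two gridded fields share the same geometry and time axis
#' @noRd
stopIfMisaligned <- function(a, b, what = "fields") {
  ok <- isTRUE(all.equal(a@lat, b@lat)) && isTRUE(all.equal(a@lon, b@lon)) &&
    identical(dim(a@data), dim(b@data)) &&
    isTRUE(all.equal(a@time$year, b@time$year)) &&
    identical(is.na(a@time$month), is.na(b@time$month)) &&
    isTRUE(all(a@time$month == b@time$month, na.rm = TRUE))
  if (!ok) stop("alignment error: ", what,
                " do not share grid geometry and time axis")
  invisible(TRUE)
}

#' Annual totals of a monthly field over a cell mask
#'
#' @param field monthly [GriddedField-class].
#' @param mask logical matrix `(lat, lon)` of cells to include; `NULL` keeps
#'   all cells.
#' @return named numeric vector of totals per year.
#' @export
annualTotals <- function(field, mask = NULL) {
  yrs <- sort(unique(field@time$year))
  if (is.null(mask)) mask <- matrix(TRUE, length(field@lat), length(field@lon))
  out <- vapply(yrs, function(y) {
    idx <- which(field@time$year == y)
    sum(vapply(idx, function(i) sum(field@data[, , i][mask]), 0))
  }, 0)
  names(out) <- yrs
  out
}

# Gaussian blur of a matrix, truncated at 3 sigma, edge-renormalised.
smoothMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(w, w)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); wt <- matrix(0, nr, nc)
  for (di in -r:r) {
    if (min(nr, nr - di) < max(1, 1 - di)) next
    si <- max(1, 1 - di):min(nr, nr - di)
    ti <- si + di
    for (dj in -r:r) {
      if (min(nc, nc - dj) < max(1, 1 - dj)) next
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      tj <- sj + dj
      kv <- k[di + r + 1, dj + r + 1]
      acc[ti, tj] <- acc[ti, tj] + kv * m[si, sj]
      wt[ti, tj] <- wt[ti, tj] + kv
    }
  }
  acc / wt
}
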