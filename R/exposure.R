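#' Construct an hourly ozone cube
#'
#' Values supplied in ppbV are converted to the canonical ppmV by
#' division by 1000.
#'
#' @param values numeric array (time x y x x) of hourly mean
#'   concentrations.
#' @param times POSIXct of hourly timestamps (length = first dim).
#' @param grid the [GridSpec-class] the field lives on.
#' @param units \code{"ppmV"} (default) or \code{"ppbV"}.
#' @return An [HourlyO3Grid-class] in ppmV.
#' @export
hourlyO3Grid <- function(values, times, grid, units = "ppmV") {
  values <- convertUnits(values, from = units)
  new("HourlyO3Grid", values = values, times = times, grid = grid,
      units = "ppmV")
}

#' @rdname o3Values
#' @param x an [HourlyO3Grid-class].
#' @return \code{o3Values}: the (time x y x x) concentration array, ppmV.
#' @export
setMethod("o3Values", "HourlyO3Grid", function(x) x@values)

#' @rdname o3Times
#' @param x an [HourlyO3Grid-class].
#' @return \code{o3Times}: POSIXct vector of hourly timestamps.
#' @export
setMethod("o3Times", "HourlyO3Grid", function(x) x@times)

#' @rdname gridSpec
#' @param x an object carrying a [GridSpec-class].
#' @return The grid geometry.
#' @export
setMethod("gridSpec", "HourlyO3Grid", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "ExposureGrid", function(x) x@grid)

#' @rdname aot40Values
#' @param x an [ExposureGrid-class].
#' @return \code{aot40Values}: the (ny x nx) AOT40 matrix, ppmV hr.
#' @export
setMethod("aot40Values", "ExposureGrid", function(x) x@aot40)

setMethod("show", "HourlyO3Grid", function(object) {
  d <- dim(object@values)
  cat("HourlyO3Grid:", d[1L], "hours x", d[2L], "x", d[3L], "cells (ppmV)\n",
      " ", format(object@times[1L], usetz = TRUE), "to",
      format(object@times[length(object@times)], usetz = TRUE), "\n",
      "  range:", format(range(object@values, na.rm = TRUE), digits = 4), "\n")
})

setMethod("show", "ExposureGrid", function(object) {
  cat("ExposureGrid (AOT40, ppmV hr): ", object@grid@ny, "x", object@grid@nx,
      "cells, threshold", object@threshold, "ppmV\n  window:",
      format(object@window@start, usetz = TRUE), "to",
      format(object@window@end, usetz = TRUE), "(",
      length(object@window@hoursOfDay), "h/day )\n  range:",
      format(range(object@aot40), digits = 4), "\n")
})

#' Convert concentrations to canonical ppmV
#'
#' ppbV inputs are divided by 1000; ppmV inputs pass through unchanged.
#' Unknown unit tags are rejected.
#'
#' @param x numeric vector/array or an [HourlyO3Grid-class].
#' @param from unit tag, \code{"ppmV"} or \code{"ppbV"}.
#' @return Same shape as \code{x}, in ppmV.
#' @examples
#' convertUnits(40, "ppbV")  # 0.04
#' @export
setMethod("convertUnits", "numeric", function(x, from) {
  switch(from,
         ppmV = x,
         ppbV = x / 1000,
         stop("unknown concentration unit tag: '", from,
              "' (expected 'ppmV' or 'ppbV')"))
})

#' @rdname convertUnits
#' @export
setMethod("convertUnits", "array", function(x, from) {
  if (!from %in% c("ppmV", "ppbV"))
    stop("unknown concentration unit tag: '", from,
         "' (expected 'ppmV' or 'ppbV')")
  if (from == "ppbV") x / 1000 else x
})

#' Define an AOT40 accumulation window
#'
#' @param start,end POSIXct or anything coercible by
#'   \code{as.POSIXct(..., tz = "UTC")}; the window is half-open,
#'   \code{[start, end)}.
#' @param hoursOfDay integer subset of 0:23; hours of the day included in
#'   the accumulation. Default all 24 hours; use e.g. \code{8:19} for the
#'   conventional daylight-only variant.
#' @return An [ExposureWindow-class].
#' @examples
#' exposureWindow("2020-05-01", "2020-08-01")           # MJJ, 24 h
#' exposureWindow("2020-05-01", "2020-08-01", 8:19)     # daylight only
#' @export
exposureWindow <- function(start, end, hoursOfDay = 0:23) {
  toT <- function(z) if (inherits(z, "POSIXct")) z else
    as.POSIXct(z, tz = "UTC")
  new("ExposureWindow", start = toT(start), end = toT(end),
      hoursOfDay = as.integer(sort(unique(hoursOfDay))))
}

#' AOT40 of a single hourly series
#'
#' The accumulated exposure over a threshold: the sum of positive
#' exceedances \code{sum(max(C_i - threshold, 0))} over hourly mean
#' concentrations, in ppmV-hours. An hour exactly at the threshold
#' contributes zero, so the ">= threshold" and "> threshold" readings of
#' the accumulation condition coincide.
#'
#' Missing values are rejected under the default strict policy. With
#' \code{naAction = "skip"} they are dropped from the sum (never
#' rescaled: AOT40 is a sum, not a mean, so skipping biases the total
#' low) and the skipped count is reported via \code{message()}.
#'
#' @param x numeric vector of hourly mean concentrations, ppmV, >= 0.
#' @param threshold exceedance threshold, ppmV; default 0.04.
#' @param naAction \code{"error"} (default) or \code{"skip"}.
#' @return AOT40 in ppmV hr (single non-negative number).
#' @examples
#' aot40Series(rep(0.05, 10))                    # 0.10
#' aot40Series(c(0.030, 0.045, 0.060, 0.041))    # 0.026
#' @export
aot40Series <- function(x, threshold = 0.04, naAction = c("error", "skip")) {
  naAction <- match.arg(naAction)
  if (!is.numeric(x)) stop("concentration series must be numeric")
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive number (ppmV)")
  nNA <- sum(is.na(x))
  if (nNA > 0L) {
    if (naAction == "error")
      stop("series contains ", nNA, " missing hour(s); set naAction='skip' ",
           "to drop them (the total is not rescaled)")
    message("aot40Series: skipped ", nNA, " missing hour(s)")
    x <- x[!is.na(x)]
  }
  if (any(x < 0)) stop("negative concentrations in series")
  sum(pmax(x - threshold, 0))
}

# Logical index of cube hours inside a window; errors name the missing span.
windowMask <- function(times, window) {
  lo <- times[1L]
  hi <- times[length(times)] + 3600
  if (window@start < lo || window@end > hi) {
    miss <- character(0)
    if (window@start < lo)
      miss <- c(miss, paste0("[", format(window@start, usetz = TRUE), ", ",
                             format(lo, usetz = TRUE), ")"))
    if (window@end > hi)
      miss <- c(miss, paste0("[", format(hi, usetz = TRUE), ", ",
                             format(window@end, usetz = TRUE), ")"))
    stop("exposure window extends beyond the cube's time range; missing span ",
         paste(miss, collapse = " and "))
  }
  hr <- as.integer(format(times, "%H", tz = "UTC"))
  times >= window@start & times < window@end & hr %in% window@hoursOfDay
}

#' Per-cell AOT40 over a growing-season window
#'
#' Applies [aot40Series()] to every grid cell over the hours selected by
#' the window (vectorised; tested against a per-cell, per-hour loop).
#'
#' @param cube an [HourlyO3Grid-class].
#' @param window an [ExposureWindow-class]; default the cube's full time
#'   range with all 24 hours.
#' @param threshold exceedance threshold, ppmV; default 0.04.
#' @param naAction missing-hour policy, as in [aot40Series()]; applied
#'   cube-wide with a single logged count.
#' @return An [ExposureGrid-class].
#' @export
aot40Grid <- function(cube, window = NULL, threshold = 0.04,
                      naAction = c("error", "skip")) {
  naAction <- match.arg(naAction)
  stopifnot(is(cube, "HourlyO3Grid"))
  times <- cube@times
  if (is.null(window))
    window <- exposureWindow(times[1L], times[length(times)] + 3600)
  sel <- windowMask(times, window)
  if (!any(sel)) stop("exposure window selects no hours")
  vals <- cube@values[sel, , , drop = FALSE]
  nNA <- sum(is.na(vals))
  if (nNA > 0L) {
    if (naAction == "error")
      stop("cube contains ", nNA, " missing in-window value(s); set ",
           "naAction='skip' to drop them")
    message("aot40Grid: skipped ", nNA, " missing value(s)")
  }
  exceed <- pmax(vals - threshold, 0)
  aot <- colSums(exceed, na.rm = TRUE, dims = 1L)   # (ny x nx)
  new("ExposureGrid", aot40 = aot, window = window,
      threshold = threshold, grid = cube@grid, naSkipped = as.integer(nNA))
}
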