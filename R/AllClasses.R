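#' @import methods
#' @importFrom stats rnorm runif rlnorm
#' @importFrom utils write.csv read.csv head
NULL

#' Census regions recognised by the pipeline
#'
#' County region labels are restricted to the five coarse U.S. regions used
#' in regional exposure/yield summaries.
#'
#' @export
REGIONS <- c("Northeast", "Midwest", "Southeast", "Southwest", "West")

#' GridSpec: geometry of a regular planar grid
#'
#' Describes an axis-aligned regular grid of square cells. Cells are
#' half-open intervals \code{[x, x + cellSize)} so they tile the domain
#' exactly without overlap. The synthetic grid stands in for a
#' chemical-transport model's regular (e.g. 12 x 12 km) output grid; the
#' coordinate frame is planar, so areas are exact Euclidean areas.
#'
#' @slot nx,ny integer, number of cells along x and y (columns, rows).
#' @slot cellSize numeric, edge length of a cell (km for the defaults).
#' @slot origin numeric length 2, (x0, y0) of the lower-left domain corner.
#' @slot crsNote character tag describing the coordinate frame ("planar"
#'   for synthetic data). Geographic inputs must be projected to an
#'   equal-area planar frame before use; the package never reprojects.
#'
#' @seealso [makeGrid()]
#' @export
setClass("GridSpec",
  representation(nx = "integer", ny = "integer", cellSize = "numeric",
                 origin = "numeric", crsNote = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@nx) != 1L || is.na(object@nx) || object@nx < 1L)
      msg <- c(msg, "nx must be a single integer >= 1")
    if (length(object@ny) != 1L || is.na(object@ny) || object@ny < 1L)
      msg <- c(msg, "ny must be a single integer >= 1")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@origin) != 2L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be two finite coordinates")
    if (length(msg)) msg else TRUE
  })

#' HourlyO3Grid: an hourly surface-ozone concentration cube
#'
#' A dense array of hourly mean ozone concentrations on a [GridSpec],
#' dimension (time, y, x), in the package's canonical unit ppmV. Inputs in
#' ppbV are divided by 1000 at ingestion ([convertUnits()],
#' [readO3Cube()]); the 0.04 ppmV AOT40 threshold then applies directly.
#'
#' @slot values numeric array (time x y x x), ppmV; non-negative, NA
#'   allowed only to represent missing hours (see [aot40Grid()] policy).
#' @slot times POSIXct, strictly increasing with an exact 1-hour step.
#' @slot grid the [GridSpec-class] the field lives on.
#' @slot units character, always \code{"ppmV"} after construction.
#'
#' @export
setClass("HourlyO3Grid",
  representation(values = "array", times = "POSIXct", grid = "GridSpec",
                 units = "character"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@values)
    if (length(d) != 3L)
      msg <- c(msg, "values must be a 3-d array (time x y x x)")
    else {
      if (d[1L] != length(object@times))
        msg <- c(msg, "time dimension does not match length(times)")
      if (d[2L] != object@grid@ny || d[3L] != object@grid@nx)
        msg <- c(msg, sprintf("spatial dims (%d x %d) do not match grid (%d x %d)",
                              d[2L], d[3L], object@grid@ny, object@grid@nx))
    }
    if (length(object@times) > 1L) {
      step <- diff(as.numeric(object@times))
      if (any(abs(step - 3600) > 1e-6))
        msg <- c(msg, "times must have an exact 1-hour cadence")
    }
    if (any(object@values < 0, na.rm = TRUE))
      msg <- c(msg, "negative concentrations are not allowed")
    if (any(is.nan(object@values)))
      msg <- c(msg, "NaN concentrations are not allowed")
    if (!identical(object@units, "ppmV"))
      msg <- c(msg, "internal unit must be ppmV (convert at ingestion)")
    if (length(msg)) msg else TRUE
  })

#' ExposureWindow: the accumulation window for AOT40
#'
#' A half-open time interval \code{[start, end)} plus the subset of clock
#' hours over which exceedances accumulate. The default growing-season
#' window is May 1 to August 1 (the three-month MJJ season) with all 24
#' hours of the day; the conventional daylight-only variant (e.g. hours
#' 8-19) is available through \code{hoursOfDay}.
#'
#' @slot start,end POSIXct; start inclusive, end exclusive.
#' @slot hoursOfDay integer subset of 0:23 used for accumulation.
#'
#' @seealso [exposureWindow()]
#' @export
setClass("ExposureWindow",
  representation(start = "POSIXct", end = "POSIXct", hoursOfDay = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!(length(object@start) == 1L && length(object@end) == 1L &&
          object@end > object@start))
      msg <- c(msg, "end must be after start")
    h <- object@hoursOfDay
    if (length(h) == 0L || anyNA(h) || any(h < 0L | h > 23L) || anyDuplicated(h))
      msg <- c(msg, "hoursOfDay must be a non-empty duplicate-free subset of 0:23")
    if (length(msg)) msg else TRUE
  })

#' ExposureGrid: per-cell AOT40 for a stated window
#'
#' The AOT40 cumulative exposure index evaluated in every grid cell, in
#' ppmV-hours, together with the window and threshold that produced it.
#'
#' @slot aot40 numeric matrix (ny x nx), ppmV hr, all values >= 0.
#' @slot window the [ExposureWindow-class] accumulated over.
#' @slot threshold numeric, the exceedance threshold in ppmV (0.04).
#' @slot grid the [GridSpec-class].
#' @slot naSkipped integer, count of missing hours skipped (0 under the
#'   default strict policy).
#'
#' @export
setClass("ExposureGrid",
  representation(aot40 = "matrix", window = "ExposureWindow",
                 threshold = "numeric", grid = "GridSpec",
                 naSkipped = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@aot40) != object@grid@ny ||
        ncol(object@aot40) != object@grid@nx)
      msg <- c(msg, "aot40 matrix dims do not match grid")
    if (any(object@aot40 < 0, na.rm = TRUE))
      msg <- c(msg, "AOT40 values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' CountySet: county polygons, regions and crop production
#'
#' Planar county polygons (possibly multi-part, no holes) in the grid's
#' coordinate frame, each with a unique FIPS-style identifier, a region
#' label from [REGIONS], and a crop production total in bushels.
#' Production \code{NA} marks a "combined/withheld" county whose
#' production cannot be attributed individually; such counties are kept
#' for exposure aggregation but excluded (with a logged count) from
#' impact totals.
#'
#' @slot countyId character, unique IDs.
#' @slot region character, one of [REGIONS] per county.
#' @slot productionBu numeric, bushels >= 0, or NA for withheld records.
#' @slot polygons list, one element per county; each element is a list of
#'   parts, each part an n x 2 coordinate matrix (open ring, simple,
#'   non-zero area).
#'
#' @seealso [makeCounties()], [readCounties()]
#' @export
setClass("CountySet",
  representation(countyId = "character", region = "character",
                 productionBu = "numeric", polygons = "list"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@countyId)
    if (anyDuplicated(object@countyId)) {
      dup <- unique(object@countyId[duplicated(object@countyId)])
      msg <- c(msg, paste0("duplicate county IDs: ", paste(dup, collapse = ", ")))
    }
    if (length(object@region) != n || length(object@productionBu) != n ||
        length(object@polygons) != n)
      msg <- c(msg, "countyId, region, productionBu, polygons lengths differ")
    bad <- setdiff(unique(object@region), REGIONS)
    if (length(bad))
      msg <- c(msg, paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
    if (any(object@productionBu < 0, na.rm = TRUE))
      msg <- c(msg, "production must be >= 0 (NA for withheld)")
    if (any(is.infinite(object@productionBu)))
      msg <- c(msg, "production must be finite")
    for (i in seq_len(min(n, length(object@polygons)))) {
      for (part in object@polygons[[i]]) {
        if (!is.matrix(part) || ncol(part) != 2L || nrow(part) < 3L) {
          msg <- c(msg, sprintf("county %s: each polygon part must be an n x 2 matrix, n >= 3",
                                object@countyId[i]))
          next
        }
        if (!isSimpleRing(part))
          msg <- c(msg, sprintf("county %s: self-intersecting polygon", object@countyId[i]))
        if (abs(ringArea(part)) <= 0)
          msg <- c(msg, sprintf("county %s: zero-area polygon", object@countyId[i]))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' AreaWeightMatrix: sparse county-by-cell area weights
#'
#' Row c holds the fraction of county c's grid-covered area lying in each
#' cell: \code{weight(c, cell) = area(polygon_c intersect cell) /
#' area(polygon_c intersect domain)}. Rows of counties overlapping the
#' domain sum to 1; counties fully outside the domain get an empty row and
#' are listed in \code{outsideCounties}. \code{coverageFraction} is the
#' fraction of each county's total area inside the grid domain, so
#' edge-of-domain counties are renormalised over their covered part but
#' remain identifiable.
#'
#' @slot weights a \code{dgCMatrix} (counties x cells); cell j of the
#'   flattened grid is column-major over the (ny x nx) field matrix.
#' @slot countyId character, row labels.
#' @slot coverageFraction numeric in [0, 1] per county.
#' @slot grid the [GridSpec-class] the weights were built on.
#' @slot outsideCounties character, IDs with zero domain overlap.
#'
#' @seealso [computeAreaWeights()]
#' @export
setClass("AreaWeightMatrix",
  representation(weights = "Matrix", countyId = "character",
                 coverageFraction = "numeric", grid = "GridSpec",
                 outsideCounties = "character"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@weights) != length(object@countyId))
      msg <- c(msg, "weight rows do not match countyId")
    if (ncol(object@weights) != object@grid@nx * object@grid@ny)
      msg <- c(msg, "weight columns do not match grid cell count")
    rs <- Matrix::rowSums(object@weights)
    inside <- !(object@countyId %in% object@outsideCounties)
    if (any(abs(rs[inside] - 1) > 1e-9))
      msg <- c(msg, "weights of in-domain counties must sum to 1 (tol 1e-9)")
    if (any(rs[!inside] != 0))
      msg <- c(msg, "outside counties must have empty weight rows")
    if (any(object@coverageFraction < 0 | object@coverageFraction > 1 + 1e-9))
      msg <- c(msg, "coverageFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' ScenarioReport: scenario comparison summary
#'
#' Holds the per-county deltas (second minus first scenario), per-region
#' (min, max) ranges, per-scenario totals with production-reduction
#' percentages, and the overall summary (production gain in USD,
#' difference in reduction, shares of counties with increased / improved /
#' unchanged losses).
#'
#' @slot labels character(2), scenario labels (reference, perturbed).
#' @slot countyDeltas data.frame of per-county differences.
#' @slot regional data.frame of per-region (min, max) ranges.
#' @slot totals data.frame, one row per scenario.
#' @slot overall named list of domain-wide summary numbers.
#' @slot price numeric, USD per bushel used for valuation.
#'
#' @seealso [buildScenarioReport()]
#' @export
setClass("ScenarioReport",
  representation(labels = "character", countyDeltas = "data.frame",
                 regional = "data.frame", totals = "data.frame",
                 overall = "list", price = "numeric"))
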