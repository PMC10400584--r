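#' Exact polygon-cell area weights for a county set
#'
#' For every county, the intersection area of its polygon with each grid
#' cell is computed by exact polygon clipping, and weights are
#' normalised over the county's grid-covered area:
#' \code{weight(c, cell) = area(poly_c int cell) / area(poly_c int domain)},
#' so each in-domain county's weights sum to 1 and the county average is
#' a true area-weighted mean. Counties partially outside the domain are
#' renormalised over the covered part and carry
#' \code{coverageFraction < 1}; counties fully outside get an empty row,
#' are listed in \code{outsideCounties}, and a count is logged.
#'
#' @param grid a [GridSpec-class].
#' @param counties a [CountySet-class] in the same (planar, equal-area)
#'   coordinate frame as the grid. Geographic data must be projected to
#'   an equal-area frame beforehand; the package does not reproject.
#' @return An [AreaWeightMatrix-class].
#' @export
computeAreaWeights <- function(grid, counties) {
  stopifnot(is(grid, "GridSpec"), is(counties, "CountySet"))
  b <- domainBounds(grid)
  cs <- grid@cellSize
  n <- length(counties)
  ti <- integer(0); tj <- integer(0); txv <- numeric(0)
  coverage <- numeric(n)
  outside <- character(0)

  for (c in seq_len(n)) {
    poly <- counties@polygons[[c]]
    totalArea <- polygonArea(poly)
    if (totalArea <= 0)
      stop("county ", counties@countyId[c], ": zero-area polygon")
    xs <- unlist(lapply(poly, function(r) r[, 1L]))
    ys <- unlist(lapply(poly, function(r) r[, 2L]))
    ix0 <- max(1L, 1L + floor((min(xs) - b["xmin"]) / cs))
    ix1 <- min(grid@nx, 1L + floor((max(xs) - b["xmin"]) / cs + 1e-12))
    iy0 <- max(1L, 1L + floor((min(ys) - b["ymin"]) / cs))
    iy1 <- min(grid@ny, 1L + floor((max(ys) - b["ymin"]) / cs + 1e-12))
    cellIdx <- integer(0); cellArea <- numeric(0)
    if (ix0 <= ix1 && iy0 <= iy1) {
      for (ix in seq(ix0, ix1)) {
        for (iy in seq(iy0, iy1)) {
          cb <- cellBounds(grid, ix, iy)
          a <- clipAreaRect(poly, cb["xmin"], cb["xmax"], cb["ymin"], cb["ymax"])
          if (a > 0) {
            cellIdx <- c(cellIdx, cellIndex(grid, ix, iy))
            cellArea <- c(cellArea, a)
          }
        }
      }
    }
    inDomain <- sum(cellArea)
    if (inDomain <= totalArea * 1e-12) {
      outside <- c(outside, counties@countyId[c])
      coverage[c] <- 0
    } else {
      ti <- c(ti, rep.int(c, length(cellIdx)))
      tj <- c(tj, cellIdx)
      txv <- c(txv, cellArea / inDomain)
      coverage[c] <- min(1, inDomain / totalArea)
    }
  }
  if (length(outside))
    message("computeAreaWeights: ", length(outside),
            " county(ies) fully outside the grid domain: ",
            paste(outside, collapse = ", "))
  W <- Matrix::sparseMatrix(i = ti, j = tj, x = txv,
                            dims = c(n, nCells(grid)))
  new("AreaWeightMatrix", weights = W, countyId = counties@countyId,
      coverageFraction = coverage, grid = grid, outsideCounties = outside)
}

#' @rdname weightMatrix
#' @param x an [AreaWeightMatrix-class].
#' @return \code{weightMatrix}: the sparse (counties x cells) matrix.
#' @export
setMethod("weightMatrix", "AreaWeightMatrix", function(x) x@weights)

#' @rdname coverageFraction
#' @param x an [AreaWeightMatrix-class].
#' @return \code{coverageFraction}: numeric in [0, 1] per county.
#' @export
setMethod("coverageFraction", "AreaWeightMatrix", function(x)
  stats::setNames(x@coverageFraction, x@countyId))

#' @rdname countyIds
#' @export
setMethod("countyIds", "AreaWeightMatrix", function(x) x@countyId)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "AreaWeightMatrix", function(x) x@grid)

setMethod("show", "AreaWeightMatrix", function(object) {
  cat("AreaWeightMatrix:", nrow(object@weights), "counties x",
      ncol(object@weights), "cells;",
      length(object@weights@x), "nonzero weights\n")
  if (length(object@outsideCounties))
    cat("  outside domain:", paste(object@outsideCounties, collapse = ", "),
        "\n")
})

#' Area-weighted county exposures
#'
#' County AOT40 is the weighted mean of overlapped cell values,
#' \code{sum(weight * cellAOT40)}; weights sum to 1 per county, so each
#' county value lies between the min and max of its overlapped cells.
#' Counties fully outside the grid are excluded from the output with a
#' logged count.
#'
#' @param exposure an [ExposureGrid-class].
#' @param weights an [AreaWeightMatrix-class] built on the same grid.
#' @return data.frame with columns \code{county_id}, \code{aot40}
#'   (ppmV hr) and \code{coverage_fraction}.
#' @export
aggregateExposure <- function(exposure, weights) {
  stopifnot(is(exposure, "ExposureGrid"), is(weights, "AreaWeightMatrix"))
  if (!sameGrid(exposure@grid, weights@grid))
    stop("exposure grid and weight grid differ")
  v <- as.vector(exposure@aot40)           # column-major = cellIndex order
  agg <- as.numeric(weights@weights %*% v)
  keep <- !(weights@countyId %in% weights@outsideCounties)
  if (any(!keep))
    message("aggregateExposure: excluded ", sum(!keep),
            " out-of-domain county(ies)")
  data.frame(county_id = weights@countyId[keep], aot40 = agg[keep],
             coverage_fraction = weights@coverageFraction[keep],
             stringsAsFactors = FALSE)
}

#' County AOT40 by either aggregation order
#'
#' The exposure index is nonlinear (thresholded), so computing AOT40 per
#' cell and then area-averaging (\code{"exposure_first"}, the default)
#' differs from area-averaging the hourly concentrations and then
#' applying the index (\code{"concentration_first"}). Both readings of
#' "averaged into a single county and weighted by area" are provided;
#' see the package vignette for why the default is exposure-first.
#'
#' @param cube an [HourlyO3Grid-class].
#' @param weights an [AreaWeightMatrix-class] on the cube's grid.
#' @param window an [ExposureWindow-class] (NULL = full range, 24 h).
#' @param threshold ppmV; default 0.04.
#' @param order \code{"exposure_first"} or \code{"concentration_first"}.
#' @param naAction missing-hour policy, as in [aot40Series()].
#' @return data.frame as from [aggregateExposure()].
#' @export
countyAOT40 <- function(cube, weights, window = NULL, threshold = 0.04,
                        order = c("exposure_first", "concentration_first"),
                        naAction = c("error", "skip")) {
  order <- match.arg(order)
  naAction <- match.arg(naAction)
  if (order == "exposure_first") {
    exposure <- aot40Grid(cube, window, threshold, naAction)
    return(aggregateExposure(exposure, weights))
  }
  stopifnot(is(weights, "AreaWeightMatrix"))
  if (!sameGrid(cube@grid, weights@grid))
    stop("cube grid and weight grid differ")
  times <- cube@times
  if (is.null(window))
    window <- exposureWindow(times[1L], times[length(times)] + 3600)
  sel <- windowMask(times, window)
  vals <- cube@values[sel, , , drop = FALSE]
  dim(vals) <- c(sum(sel), nCells(cube@grid))   # time x cells, cellIndex order
  series <- as.matrix(vals %*% Matrix::t(weights@weights))  # time x counties
  keep <- !(weights@countyId %in% weights@outsideCounties)
  if (any(!keep))
    message("countyAOT40: excluded ", sum(!keep),
            " out-of-domain county(ies)")
  aot <- vapply(which(keep), function(c)
    aot40Series(series[, c], threshold, naAction), numeric(1))
  data.frame(county_id = weights@countyId[keep], aot40 = aot,
             coverage_fraction = weights@coverageFraction[keep],
             stringsAsFactors = FALSE)
}
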