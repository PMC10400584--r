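#' Construct a regular planar grid
#'
#' @param nx,ny number of cells along x and y; must be >= 1.
#' @param cellSize edge length of a (square) cell; must be > 0. The
#'   defaults elsewhere in the package treat this as km.
#' @param origin numeric length 2, coordinates of the lower-left corner
#'   of the domain.
#' @param crsNote free-text tag for the coordinate frame; synthetic data
#'   uses \code{"planar"}.
#' @return A [GridSpec-class].
#' @examples
#' g <- makeGrid(4, 3, 12)
#' cellCenters(g)
#' @export
makeGrid <- function(nx, ny, cellSize, origin = c(0, 0), crsNote = "planar") {
  if (length(nx) != 1L || length(ny) != 1L || is.na(nx) || is.na(ny) ||
      nx < 1 || ny < 1 || nx != round(nx) || ny != round(ny))
    stop("grid dimensions nx, ny must be positive integers (got nx=",
         nx, ", ny=", ny, ")")
  if (length(cellSize) != 1L || !is.finite(cellSize) || cellSize <= 0)
    stop("cellSize must be a single positive number (got ", cellSize, ")")
  new("GridSpec", nx = as.integer(nx), ny = as.integer(ny),
      cellSize = as.numeric(cellSize), origin = as.numeric(origin),
      crsNote = as.character(crsNote))
}

#' Cell-centre coordinates of a grid
#'
#' Centres are \code{origin + (i - 0.5) * cellSize} along each axis.
#'
#' @param x a [GridSpec-class].
#' @return A list with vectors \code{x} (length nx) and \code{y}
#'   (length ny).
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  list(x = x@origin[1L] + (seq_len(x@nx) - 0.5) * x@cellSize,
       y = x@origin[2L] + (seq_len(x@ny) - 0.5) * x@cellSize)
})

#' Bounding box of the grid domain
#'
#' @param x a [GridSpec-class].
#' @return Named numeric \code{c(xmin, xmax, ymin, ymax)}.
#' @export
setMethod("domainBounds", "GridSpec", function(x) {
  c(xmin = x@origin[1L], xmax = x@origin[1L] + x@nx * x@cellSize,
    ymin = x@origin[2L], ymax = x@origin[2L] + x@ny * x@cellSize)
})

#' Number of cells in a grid
#'
#' @param grid a [GridSpec-class].
#' @return Integer, \code{nx * ny}.
#' @export
nCells <- function(grid) grid@nx * grid@ny

#' Flattened cell index
#'
#' Cells are indexed column-major over the (ny x nx) field matrix, i.e.
#' \code{index = iy + (ix - 1) * ny}, matching \code{as.vector()} of a
#' field matrix. All sparse weight matrices use this ordering.
#'
#' @param grid a [GridSpec-class].
#' @param ix,iy 1-based column (x) and row (y) cell indices.
#' @return Integer index into the flattened grid.
#' @export
cellIndex <- function(grid, ix, iy) as.integer(iy + (ix - 1L) * grid@ny)

#' Bounds of a single cell
#'
#' @param grid a [GridSpec-class].
#' @param ix,iy 1-based cell indices.
#' @return Named numeric \code{c(xmin, xmax, ymin, ymax)}; cells are
#'   half-open on their upper edges.
#' @export
cellBounds <- function(grid, ix, iy) {
  cs <- grid@cellSize
  c(xmin = grid@origin[1L] + (ix - 1) * cs,
    xmax = grid@origin[1L] + ix * cs,
    ymin = grid@origin[2L] + (iy - 1) * cs,
    ymax = grid@origin[2L] + iy * cs)
}

setMethod("show", "GridSpec", function(object) {
  b <- domainBounds(object)
  cat("GridSpec:", object@nx, "x", object@ny, "cells of size",
      object@cellSize, "\n  domain: x [", b["xmin"], ",", b["xmax"],
      ") y [", b["ymin"], ",", b["ymax"], ")  crs:", object@crsNote, "\n")
})

sameGrid <- function(a, b, tol = 1e-9) {
  a@nx == b@nx && a@ny == b@ny &&
    abs(a@cellSize - b@cellSize) <= tol &&
    all(abs(a@origin - b@origin) <= tol)
}
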