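# Small programmatic fixtures shared across test files.

# Hourly cube of uniform random concentrations straddling the 0.04 ppmV
# threshold, starting 2020-05-01 00:00 UTC.
tinyCube <- function(seed, nx = 3, ny = 3, nt = 48, lo = 0.02, hi = 0.06,
                     cellSize = 1) {
  set.seed(seed)
  grid <- makeGrid(nx, ny, cellSize)
  vals <- array(runif(nt * ny * nx, lo, hi), dim = c(nt, ny, nx))
  times <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC") + 3600 * (seq_len(nt) - 1)
  hourlyO3Grid(vals, times, grid)
}

# Independent AOT40 oracle: explicit per-cell, per-hour accumulation.
aot40LoopOracle <- function(values, threshold = 0.04) {
  nt <- dim(values)[1]; ny <- dim(values)[2]; nx <- dim(values)[3]
  out <- matrix(0, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      acc <- 0
      for (t in seq_len(nt)) {
        d <- values[t, iy, ix] - threshold
        if (d > 0) acc <- acc + d
      }
      out[iy, ix] <- acc
    }
  }
  out
}

# A random simple polygon: axis-aligned rectangle, L-shape, or the
# convex hull of random points (always simple).
randomSimplePolygon <- function(seed, bounds = c(0, 3, 0, 3)) {
  set.seed(seed)
  kind <- sample(c("rect", "L", "hull"), 1)
  xr <- sort(runif(2, bounds[1], bounds[2]))
  yr <- sort(runif(2, bounds[3], bounds[4]))
  if (kind == "rect") return(rectRing(xr[1], xr[2], yr[1], yr[2]))
  if (kind == "L") {
    xm <- runif(1, xr[1] + 0.2 * diff(xr), xr[2] - 0.2 * diff(xr))
    ym <- runif(1, yr[1] + 0.2 * diff(yr), yr[2] - 0.2 * diff(yr))
    return(matrix(c(xr[1], yr[1],  xr[2], yr[1],  xr[2], ym,
                    xm, ym,  xm, yr[2],  xr[1], yr[2]),
                  ncol = 2, byrow = TRUE))
  }
  pts <- cbind(runif(12, xr[1], xr[2]), runif(12, yr[1], yr[2]))
  pts[rev(chull(pts)), , drop = FALSE]   # counter-clockwise hull
}

# Monte-Carlo area-weight oracle using sp::point.in.polygon (an
# implementation independent of the package's clipping code): fraction
# of in-polygon points falling in each grid cell.
mcWeightsOracle <- function(poly, grid, n = 1e5, seed = 1) {
  set.seed(seed)
  xs <- poly[, 1]; ys <- poly[, 2]
  px <- runif(n, min(xs), max(xs))
  py <- runif(n, min(ys), max(ys))
  inside <- sp::point.in.polygon(px, py, xs, ys) > 0
  px <- px[inside]; py <- py[inside]
  b <- domainBounds(grid)
  ok <- px >= b["xmin"] & px < b["xmax"] & py >= b["ymin"] & py < b["ymax"]
  px <- px[ok]; py <- py[ok]
  ix <- pmin(grid@nx, 1 + floor((px - b["xmin"]) / grid@cellSize))
  iy <- pmin(grid@ny, 1 + floor((py - b["ymin"]) / grid@cellSize))
  idx <- cellIndex(grid, ix, iy)
  w <- numeric(nCells(grid))
  tab <- table(idx)
  w[as.integer(names(tab))] <- as.numeric(tab) / length(px)
  w
}

# Tiny hand-checkable impact table.
handImpactTable <- function(aot40, production, region = "Midwest",
                            params = doseResponseParams()) {
  n <- length(aot40)
  ryl <- params$a * aot40
  loss <- if (params$convention == "compensated")
    production * ryl / (1 - ryl) else production * ryl
  data.frame(county_id = sprintf("%05d", seq_len(n)),
             region = rep_len(region, n), production_bu = production,
             aot40 = aot40, ryl = ryl, loss_bu = loss,
             loss_usd = loss * params$priceUsdPerBu,
             stringsAsFactors = FALSE)
}
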