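# Synthetic inputs: hourly ozone fields with a photochemical diurnal
# cycle, spatially correlated noise and regionally signed scenario
# deltas; rectilinear county tessellations with region labels and crop
# production. These emulate the statistical structure of
# chemical-transport-model output and county production records so the
# downstream exposure -> impact stages are fully testable offline.

#' Configuration for a pair of synthetic scenario fields
#'
#' Defaults describe a three-month (May-July, 92-day) growing season with
#' a mean ozone level of 35 ppbV, a 15 ppbV diurnal swing peaking
#' mid-afternoon, and spatially correlated noise — a plausible rural
#' summer ozone climate. Scenario deltas default to the regionally signed
#' pattern seen in emissions-slowdown studies: about -1 ppbV over the
#' Midwest and up to +3 ppbV over the Southeast.
#'
#' @param seed integer; fully determines the generated fields.
#' @param nDays number of days (24 hourly steps each); default 92
#'   (May 1 through July 31).
#' @param baselineMean mean concentration, ppmV; default 0.035.
#' @param diurnalAmplitude amplitude of the sinusoidal diurnal cycle,
#'   ppmV; maximum at hour 15 local, minimum at hour 03. Default 0.015.
#' @param spatialCorrLength correlation length of the noise field in
#'   cells (Gaussian smoothing scale); 0 disables smoothing. Default 3.
#' @param noiseSd standard deviation of the white noise before
#'   smoothing, ppmV; default 0.004.
#' @param deltaRegions list of \code{list(polygon =, offset =)} pairs;
#'   each offset (ppmV) is added to the perturbed scenario in every cell
#'   whose centre falls inside the polygon. Overlapping polygons sum.
#'   \code{NULL} means no perturbation.
#' @param scenarioLabels character(2), names for (baseline, perturbed);
#'   default \code{c("BAU", "C19")}.
#' @param clipNegative clip negative concentrations to 0 after
#'   perturbation (count reported via \code{message()}); default TRUE.
#' @param startTime POSIXct of the first hour; default
#'   2020-05-01 00:00 UTC.
#' @return A validated config list of class \code{"ScenarioFieldConfig"}.
#' @export
scenarioFieldConfig <- function(seed = 1L, nDays = 92L,
                                baselineMean = 0.035,
                                diurnalAmplitude = 0.015,
                                spatialCorrLength = 3,
                                noiseSd = 0.004,
                                deltaRegions = NULL,
                                scenarioLabels = c("BAU", "C19"),
                                clipNegative = TRUE,
                                startTime = as.POSIXct("2020-05-01 00:00:00",
                                                       tz = "UTC")) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            nDays >= 1, baselineMean >= 0, diurnalAmplitude >= 0,
            spatialCorrLength >= 0, noiseSd >= 0,
            length(scenarioLabels) == 2L,
            scenarioLabels[1L] != scenarioLabels[2L])
  if (!is.null(deltaRegions)) {
    for (d in deltaRegions)
      stopifnot(is.list(d), !is.null(d$polygon), is.numeric(d$offset),
                length(d$offset) == 1L)
  }
  structure(list(seed = as.integer(seed), nDays = as.integer(nDays),
                 baselineMean = baselineMean,
                 diurnalAmplitude = diurnalAmplitude,
                 spatialCorrLength = spatialCorrLength, noiseSd = noiseSd,
                 deltaRegions = deltaRegions,
                 scenarioLabels = scenarioLabels,
                 clipNegative = clipNegative, startTime = startTime),
            class = "ScenarioFieldConfig")
}

# Row-normalised 1-d Gaussian smoothing matrix (n x n), scale L cells.
gaussSmoother <- function(n, L) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, function(a, b) (a - b)^2) / (2 * L^2))
  K / rowSums(K)
}

#' Generate a pair of hourly ozone cubes for two emissions scenarios
#'
#' The baseline field is \code{baselineMean + diurnal(hour) + noise},
#' where the diurnal term is
#' \code{diurnalAmplitude * sin(2 * pi * (hour - 9) / 24)} (maximum at
#' hour 15, minimum at hour 03) and the noise is white Gaussian noise
#' smoothed over \code{spatialCorrLength} cells. The perturbed field is
#' the baseline plus each configured delta inside its polygon (summed
#' where polygons overlap), so outside all delta polygons the two
#' scenarios are bit-identical. Negative values are clipped to zero
#' (count logged) unless clipping is disabled. The same seed always
#' reproduces the same pair.
#'
#' @param grid a [GridSpec-class].
#' @param cfg a [scenarioFieldConfig()] list.
#' @return Named list of two [HourlyO3Grid-class] cubes
#'   (\code{cfg$scenarioLabels}).
#' @export
generateScenarioFields <- function(grid, cfg) {
  stopifnot(is(grid, "GridSpec"), inherits(cfg, "ScenarioFieldConfig"))
  nt <- 24L * cfg$nDays
  ny <- grid@ny; nx <- grid@nx
  times <- cfg$startTime + 3600 * (seq_len(nt) - 1)

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(cfg$seed)

  noise <- array(rnorm(nt * ny * nx, sd = cfg$noiseSd), dim = c(nt, ny, nx))
  if (cfg$spatialCorrLength > 0 && (ny > 1L || nx > 1L)) {
    Ky <- gaussSmoother(ny, cfg$spatialCorrLength)
    Kx <- gaussSmoother(nx, cfg$spatialCorrLength)
    for (t in seq_len(nt))
      noise[t, , ] <- Ky %*% noise[t, , ] %*% t(Kx)
  }

  hour <- as.integer(format(times, "%H", tz = "UTC"))
  diurnal <- cfg$diurnalAmplitude * sin(2 * pi * (hour - 9) / 24)
  base <- array(0, dim = c(nt, ny, nx))
  for (t in seq_len(nt)) base[t, , ] <- cfg$baselineMean + diurnal[t]
  base <- base + noise

  deltaField <- matrix(0, ny, nx)
  if (length(cfg$deltaRegions)) {
    cc <- cellCenters(grid)
    px <- rep(cc$x, each = ny)
    py <- rep(cc$y, times = nx)
    for (d in cfg$deltaRegions) {
      inPoly <- pointsInPolygon(px, py, d$polygon)
      deltaField <- deltaField + d$offset * matrix(inPoly, ny, nx)
    }
  }
  pert <- base + rep(deltaField, each = nt)

  clip <- function(a, label) {
    nNeg <- sum(a < 0)
    if (nNeg > 0L) {
      if (!cfg$clipNegative)
        stop("scenario '", label, "' has ", nNeg,
             " negative value(s) and clipping is disabled")
      message("generateScenarioFields [", label, "]: clipped ", nNeg,
              " negative value(s) to 0")
      a[a < 0] <- 0
    }
    a
  }
  if (cfg$clipNegative) {
    base <- clip(base, cfg$scenarioLabels[1L])
    pert <- clip(pert, cfg$scenarioLabels[2L])
  }
  if (anyNA(base) || anyNA(pert))
    stop("internal failure: NaN produced in synthetic field")

  out <- list(hourlyO3Grid(base, times, grid),
              hourlyO3Grid(pert, times, grid))
  names(out) <- cfg$scenarioLabels
  out
}

#' Rectangular region layout over a grid domain
#'
#' Partitions the domain into five rectangles arranged like the coarse
#' CONUS regions: West along the left edge, Southwest and Southeast
#' across the south, Midwest and Northeast across the north.
#'
#' @param grid a [GridSpec-class].
#' @return Named list of open rectangular rings, names = [REGIONS].
#' @export
regionPolygons <- function(grid) {
  b <- domainBounds(grid)
  fx <- function(f) b["xmin"] + f * (b["xmax"] - b["xmin"])
  fy <- function(f) b["ymin"] + f * (b["ymax"] - b["ymin"])
  list(West      = rectRing(fx(0),    fx(0.20), fy(0),    fy(1)),
       Southwest = rectRing(fx(0.20), fx(0.45), fy(0),    fy(0.45)),
       Southeast = rectRing(fx(0.45), fx(1),    fy(0),    fy(0.45)),
       Midwest   = rectRing(fx(0.20), fx(0.70), fy(0.45), fy(1)),
       Northeast = rectRing(fx(0.70), fx(1),    fy(0.45), fy(1)))
}

# Region of each centroid under the regionPolygons() layout.
assignRegions <- function(grid, cx, cy) {
  b <- domainBounds(grid)
  fx <- (cx - b["xmin"]) / (b["xmax"] - b["xmin"])
  fy <- (cy - b["ymin"]) / (b["ymax"] - b["ymin"])
  ifelse(fx < 0.20, "West",
    ifelse(fy < 0.45,
      ifelse(fx < 0.45, "Southwest", "Southeast"),
      ifelse(fx < 0.70, "Midwest", "Northeast")))
}

#' Construct a CountySet
#'
#' @param countyId character vector of unique IDs.
#' @param region character vector of labels from [REGIONS].
#' @param productionBu numeric bushels, >= 0 or NA (withheld record).
#' @param polygons list, one entry per county: a single open ring matrix
#'   or a list of ring matrices (multi-part).
#' @return A validated [CountySet-class].
#' @export
countySet <- function(countyId, region, productionBu, polygons) {
  polygons <- lapply(polygons, function(p) if (is.matrix(p)) list(p) else p)
  new("CountySet", countyId = as.character(countyId),
      region = as.character(region),
      productionBu = as.numeric(productionBu), polygons = polygons)
}

#' @rdname countyIds
#' @param x a [CountySet-class].
#' @return \code{countyIds}: character vector of IDs.
#' @export
setMethod("countyIds", "CountySet", function(x) x@countyId)

#' @rdname countyRegions
#' @param x a [CountySet-class].
#' @return \code{countyRegions}: character vector of region labels.
#' @export
setMethod("countyRegions", "CountySet", function(x) x@region)

#' @rdname productionBu
#' @param x a [CountySet-class].
#' @return \code{productionBu}: numeric bushels (NA = withheld).
#' @export
setMethod("productionBu", "CountySet", function(x) x@productionBu)

#' @rdname countyPolygons
#' @param x a [CountySet-class].
#' @return \code{countyPolygons}: list of lists of ring matrices.
#' @export
setMethod("countyPolygons", "CountySet", function(x) x@polygons)

#' @export
setMethod("length", "CountySet", function(x) length(x@countyId))

setMethod("show", "CountySet", function(object) {
  cat("CountySet:", length(object@countyId), "counties\n")
  tab <- table(object@region)
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  nNA <- sum(is.na(object@productionBu))
  cat("  production:", format(sum(object@productionBu, na.rm = TRUE),
                              big.mark = ","), "Bu total;",
      nNA, "withheld record(s)\n")
})

#' Tessellate a grid domain into synthetic counties
#'
#' Splits the domain into \code{nCountyX x nCountyY} rectangular
#' counties. With \code{snap = TRUE} county boundaries fall exactly on
#' cell edges (every cell belongs wholly to one county); with
#' \code{snap = FALSE} interior boundaries are jittered off the cell
#' lattice so fractional polygon-cell overlaps are exercised. Regions
#' follow the [regionPolygons()] layout by county centroid. Production is
#' drawn per region from log-normal distributions calibrated so that
#' Midwest and Southeast counties dominate (as U.S. soybean production
#' does), Northeast counties are modest, and Southwest/West counties grow
#' none.
#'
#' @param grid a [GridSpec-class].
#' @param nCountyX,nCountyY tessellation dimensions.
#' @param seed integer; determines jitter, production draws and withheld
#'   picks.
#' @param snap snap county boundaries to cell edges (default TRUE).
#' @param jitterFrac with \code{snap = FALSE}, boundary jitter amplitude
#'   as a fraction of the cell size (default 0.4).
#' @param nWithheld number of producing counties whose production is
#'   masked to NA, emulating combined/withheld records (default 0).
#' @param production optional numeric vector (length = number of
#'   counties, row-major from the south-west corner) overriding the
#'   random production draws.
#' @return A [CountySet-class].
#' @export
makeCounties <- function(grid, nCountyX, nCountyY, seed = 1L, snap = TRUE,
                         jitterFrac = 0.4, nWithheld = 0L,
                         production = NULL) {
  stopifnot(is(grid, "GridSpec"), nCountyX >= 1, nCountyY >= 1)
  b <- domainBounds(grid)
  cs <- grid@cellSize

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(as.integer(seed))

  edges <- function(lo, hi, nSeg) {
    e <- seq(lo, hi, length.out = nSeg + 1L)
    if (nSeg > 1L) {
      mid <- e[-c(1L, nSeg + 1L)]
      if (!snap) {
        mid <- mid + runif(length(mid), -jitterFrac, jitterFrac) * cs
        mid <- pmin(pmax(mid, lo + 0.1 * cs), hi - 0.1 * cs)
      } else {
        mid <- lo + round((mid - lo) / cs) * cs
      }
      e <- c(e[1L], sort(mid), e[nSeg + 1L])
      if (anyDuplicated(e)) stop("degenerate tessellation: duplicate edges")
    }
    e
  }
  ex <- edges(b["xmin"], b["xmax"], nCountyX)
  ey <- edges(b["ymin"], b["ymax"], nCountyY)

  n <- nCountyX * nCountyY
  ids <- character(n); regs <- character(n); polys <- vector("list", n)
  cx <- numeric(n); cy <- numeric(n)
  k <- 0L
  for (jy in seq_len(nCountyY)) {
    for (jx in seq_len(nCountyX)) {
      k <- k + 1L
      ids[k] <- sprintf("%02d%03d", jy, jx)   # FIPS-style state+county digits
      polys[[k]] <- rectRing(ex[jx], ex[jx + 1L], ey[jy], ey[jy + 1L])
      cx[k] <- (ex[jx] + ex[jx + 1L]) / 2
      cy[k] <- (ey[jy] + ey[jy + 1L]) / 2
    }
  }
  regs <- assignRegions(grid, cx, cy)

  if (is.null(production)) {
    production <- numeric(n)
    for (k in seq_len(n)) {
      production[k] <- switch(regs[k],
        Midwest   = rlnorm(1, meanlog = log(2.5e6), sdlog = 0.6),
        Southeast = rlnorm(1, meanlog = log(1.2e6), sdlog = 0.7),
        Northeast = rlnorm(1, meanlog = log(3e5),  sdlog = 0.8),
        0)
    }
    production <- round(production)
  } else {
    stopifnot(length(production) == n)
  }

  if (nWithheld > 0L) {
    cand <- which(production > 0)
    if (length(cand) < nWithheld)
      stop("cannot withhold ", nWithheld, " counties: only ",
           length(cand), " have production")
    production[sample(cand, nWithheld)] <- NA_real_
  }
  countySet(ids, regs, production, polys)
}

#' Default scenario perturbation for a grid
#'
#' The regionally signed delta pattern used as the study condition:
#' -0.001 ppmV (-1 ppbV) over the Midwest rectangle and +0.003 ppmV
#' (+3 ppbV) over the Southeast rectangle of the [regionPolygons()]
#' layout.
#'
#' @param grid a [GridSpec-class].
#' @return A \code{deltaRegions} list for [scenarioFieldConfig()].
#' @export
defaultDeltaRegions <- function(grid) {
  rp <- regionPolygons(grid)
  list(list(polygon = rp$Midwest,   offset = -0.001),
       list(polygon = rp$Southeast, offset = +0.003))
}
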