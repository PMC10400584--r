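# Readers/writers binding the pipeline stages to files: CF-style NetCDF
# for hourly cubes, GeoJSON for counties, CSV (with a JSON metadata
# comment line) for exposure grids, YAML for configuration.

TIME_UNITS_PREFIX <- "hours since "

#' Write an hourly ozone cube to NetCDF
#'
#' CF-style layout: dimensions \code{time}/\code{y}/\code{x} (time in
#' hours since the cube's first timestamp; y/x hold cell-centre
#' coordinates), variable \code{o3} with a \code{units} attribute, and
#' grid geometry in global attributes. Double precision, so a write/read
#' round trip is bit-identical.
#'
#' @param cube an [HourlyO3Grid-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeO3Cube <- function(cube, path) {
  stopifnot(is(cube, "HourlyO3Grid"))
  g <- cube@grid
  cc <- cellCenters(g)
  epoch <- format(cube@times[1L], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  hours <- as.numeric(difftime(cube@times, cube@times[1L], units = "hours"))
  dTime <- ncdf4::ncdim_def("time", paste0(TIME_UNITS_PREFIX, epoch, " UTC"),
                            hours, unlim = FALSE)
  dY <- ncdf4::ncdim_def("y", "km", cc$y)
  dX <- ncdf4::ncdim_def("x", "km", cc$x)
  vO3 <- ncdf4::ncvar_def("o3", "ppmV", list(dX, dY, dTime),
                          prec = "double",
                          longname = "hourly mean surface ozone")
  nc <- ncdf4::nc_create(path, vO3)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vO3, aperm(cube@values, c(3L, 2L, 1L)))
  ncdf4::ncatt_put(nc, 0, "cell_size", g@cellSize)
  ncdf4::ncatt_put(nc, 0, "origin_x", g@origin[1L])
  ncdf4::ncatt_put(nc, 0, "origin_y", g@origin[2L])
  ncdf4::ncatt_put(nc, 0, "crs_note", g@crsNote)
  invisible(path)
}

#' Read an hourly ozone cube from NetCDF
#'
#' Requires \code{time}/\code{y}/\code{x} dimensions, a \code{units}
#' attribute on the concentration variable (\code{ppmV} or \code{ppbV};
#' ppbV values are divided by 1000 on ingestion), and an exact 1-hour
#' cadence. Violations are rejected naming the file and variable.
#'
#' @param path NetCDF file path.
#' @param varName concentration variable name; default \code{"o3"}.
#' @return An [HourlyO3Grid-class] in ppmV.
#' @export
readO3Cube <- function(path, varName = "o3") {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!varName %in% names(nc$var))
    stop("file ", path, " has no variable '", varName, "'")
  u <- ncdf4::ncatt_get(nc, varName, "units")
  if (!u$hasatt)
    stop("file ", path, " variable '", varName, "' lacks a units attribute")
  vals <- ncdf4::ncvar_get(nc, varName, collapse_degen = FALSE)
  dimNames <- vapply(nc$var[[varName]]$dim, function(d) d$name, "")
  if (!identical(dimNames, c("x", "y", "time")))
    stop("file ", path, " variable '", varName,
         "' must have dims (x, y, time); found (",
         paste(dimNames, collapse = ", "), ")")
  tdim <- nc$dim$time
  if (!startsWith(tdim$units, TIME_UNITS_PREFIX))
    stop("file ", path, " time units must be '", TIME_UNITS_PREFIX,
         "<epoch>'; found '", tdim$units, "'")
  epoch <- as.POSIXct(sub(" UTC$", "", sub(TIME_UNITS_PREFIX, "", tdim$units)),
                      tz = "UTC")
  hours <- tdim$vals
  if (length(hours) > 1L && any(abs(diff(hours) - 1) > 1e-9))
    stop("file ", path, " variable '", varName,
         "': non-hourly time cadence (steps of ",
         paste(unique(round(diff(hours), 6)), collapse = ", "), " h)")
  times <- epoch + 3600 * hours
  xs <- nc$dim$x$vals; ys <- nc$dim$y$vals
  cellSize <- if (length(xs) > 1L) xs[2L] - xs[1L]
    else if (length(ys) > 1L) ys[2L] - ys[1L]
    else 2 * xs[1L]
  att <- function(name, default) {
    a <- ncdf4::ncatt_get(nc, 0, name)
    if (a$hasatt) a$value else default
  }
  cellSize <- att("cell_size", cellSize)
  grid <- makeGrid(length(xs), length(ys), cellSize,
                   origin = c(att("origin_x", xs[1L] - cellSize / 2),
                              att("origin_y", ys[1L] - cellSize / 2)),
                   crsNote = att("crs_note", "planar"))
  vals <- aperm(vals, c(3L, 2L, 1L))
  if (any(vals < 0, na.rm = TRUE))
    stop("file ", path, " variable '", varName,
         "' contains negative concentrations")
  hourlyO3Grid(vals, times, grid, units = u$value)
}

#' Write a county set as GeoJSON
#'
#' A FeatureCollection of MultiPolygon features with properties
#' \code{county_id}, \code{region}, \code{production_bu} (null for
#' withheld records).
#'
#' @param counties a [CountySet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCounties <- function(counties, path) {
  stopifnot(is(counties, "CountySet"))
  features <- lapply(seq_len(length(counties)), function(i) {
    coords <- lapply(counties@polygons[[i]], function(ring) {
      closed <- rbind(ring, ring[1L, , drop = FALSE])
      list(lapply(seq_len(nrow(closed)), function(k) closed[k, ]))
    })
    prod <- counties@productionBu[i]
    list(type = "Feature",
         properties = list(county_id = counties@countyId[i],
                           region = counties@region[i],
                           production_bu = if (is.na(prod)) NULL else prod),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection",
                                features = features),
                           auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a county set from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features with properties
#' \code{county_id}, \code{region} and \code{production_bu}. A missing
#' or null production marks the county as combined/withheld (kept, with
#' production NA, and excluded later at the impact stage); the count is
#' logged. Duplicate IDs, unknown regions, malformed or self-intersecting
#' geometry are rejected by [CountySet-class] validation. Interior rings
#' (holes) are not supported.
#'
#' @param path GeoJSON file path.
#' @return A [CountySet-class].
#' @export
readCounties <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("file ", path, " is not a GeoJSON FeatureCollection")
  n <- length(gj$features)
  ids <- character(n); regs <- character(n); prod <- numeric(n)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    f <- gj$features[[i]]
    p <- f$properties
    if (is.null(p$county_id) || is.null(p$region))
      stop("feature ", i, " in ", path, " lacks county_id/region")
    ids[i] <- p$county_id
    regs[i] <- p$region
    prod[i] <- if (is.null(p$production_bu)) NA_real_ else p$production_bu
    geom <- f$geometry
    ringToMatrix <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt)
        c(pt[[1L]], pt[[2L]])))
      # drop the closing vertex GeoJSON requires
      if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ]))
        m <- m[-nrow(m), , drop = FALSE]
      m
    }
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", ids[i], " in ", path, ": unsupported geometry type '",
           geom$type, "'"))
    polys[[i]] <- lapply(parts, function(part) {
      if (length(part) > 1L)
        stop("feature ", ids[i], " in ", path,
             ": polygons with holes are not supported")
      ringToMatrix(part[[1L]])
    })
  }
  nWithheld <- sum(is.na(prod))
  if (nWithheld > 0L)
    message("readCounties: ", nWithheld,
            " county(ies) flagged combined/withheld (production missing)")
  countySet(ids, regs, prod, polys)
}

#' Write an exposure grid as CSV
#'
#' A `#`-prefixed JSON metadata line (grid geometry, window, threshold)
#' followed by the (ny x nx) AOT40 matrix, row 1 = southernmost row.
#' Used to pass exposure fields between command-line stages.
#'
#' @param exposure an [ExposureGrid-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExposureGrid <- function(exposure, path) {
  stopifnot(is(exposure, "ExposureGrid"))
  g <- exposure@grid
  w <- exposure@window
  meta <- jsonlite::toJSON(list(
    nx = g@nx, ny = g@ny, cell_size = g@cellSize, origin = g@origin,
    crs_note = g@crsNote, threshold_ppmv = exposure@threshold,
    window_start = format(w@start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    window_end = format(w@end, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    hours_of_day = w@hoursOfDay, na_skipped = exposure@naSkipped),
    auto_unbox = TRUE, digits = NA)
  rows <- apply(exposure@aot40, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste0("# ", as.character(meta)), rows), path)
  invisible(path)
}

#' Read an exposure grid written by [writeExposureGrid()]
#'
#' @param path CSV file path.
#' @return An [ExposureGrid-class].
#' @export
readExposureGrid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "# "))
    stop("file ", path, " lacks the exposure metadata header line")
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1L]))
  vals <- do.call(rbind, lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]])))
  grid <- makeGrid(meta$nx, meta$ny, meta$cell_size, meta$origin,
                   meta$crs_note)
  window <- exposureWindow(as.POSIXct(meta$window_start, tz = "UTC"),
                           as.POSIXct(meta$window_end, tz = "UTC"),
                           meta$hours_of_day)
  new("ExposureGrid", aot40 = vals, window = window,
      threshold = meta$threshold_ppmv, grid = grid,
      naSkipped = as.integer(meta$na_skipped))
}
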