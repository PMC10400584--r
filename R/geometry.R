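# Planar polygon primitives used by the area-weighting stage. County
# geometries are lists of parts; a part is an open ring (n x 2 matrix,
# last vertex != first). Holes are not supported: synthetic counties and
# county GeoJSON exports are simple rings.

#' Signed area of a polygon ring (shoelace formula)
#'
#' @param ring n x 2 coordinate matrix, open (no repeated last vertex).
#' @return Signed area; positive for counter-clockwise rings.
#' @keywords internal
ringArea <- function(ring) {
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(ring[j, 1L] * ring[, 2L] - ring[, 1L] * ring[j, 2L]) / 2
}

#' Area of a (possibly multi-part) polygon
#'
#' Parts are assumed disjoint and hole-free, so areas add.
#'
#' @param poly list of open rings.
#' @return Total unsigned area.
#' @export
polygonArea <- function(poly) {
  if (is.matrix(poly)) poly <- list(poly)
  sum(vapply(poly, function(r) abs(ringArea(r)), numeric(1)))
}

# Clip a ring against one half-plane (Sutherland-Hodgman step).
# side: "xmin" keeps x >= bound, "xmax" keeps x <= bound, likewise y.
clipRingHalfplane <- function(ring, side, bound) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  coord <- if (side %in% c("xmin", "xmax")) ring[, 1L] else ring[, 2L]
  inside <- if (side %in% c("xmin", "ymin")) coord >= bound else coord <= bound
  out <- matrix(0, 2L * n, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    P <- ring[j, ]; C <- ring[i, ]
    if (inside[i]) {
      if (!inside[j]) {
        k <- k + 1L; out[k, ] <- edgeIntersection(P, C, side, bound)
      }
      k <- k + 1L; out[k, ] <- C
    } else if (inside[j]) {
      k <- k + 1L; out[k, ] <- edgeIntersection(P, C, side, bound)
    }
  }
  out[seq_len(k), , drop = FALSE]
}

edgeIntersection <- function(P, C, side, bound) {
  if (side %in% c("xmin", "xmax")) {
    t <- (bound - P[1L]) / (C[1L] - P[1L])
    c(bound, P[2L] + t * (C[2L] - P[2L]))
  } else {
    t <- (bound - P[2L]) / (C[2L] - P[2L])
    c(P[1L] + t * (C[1L] - P[1L]), bound)
  }
}

#' Clip a ring to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four rectangle edges. For a
#' non-convex subject ring the result may contain degenerate (zero-width)
#' bridges, but its signed area still equals the true intersection area,
#' which is all the weighting stage needs.
#'
#' @param ring open n x 2 ring.
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return Clipped ring (possibly 0-row).
#' @keywords internal
clipRingRect <- function(ring, xmin, xmax, ymin, ymax) {
  r <- clipRingHalfplane(ring, "xmin", xmin)
  r <- clipRingHalfplane(r, "xmax", xmax)
  r <- clipRingHalfplane(r, "ymin", ymin)
  clipRingHalfplane(r, "ymax", ymax)
}

#' Intersection area of a polygon and a rectangle
#'
#' @param poly list of open rings (or a single matrix).
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return Unsigned intersection area.
#' @export
clipAreaRect <- function(poly, xmin, xmax, ymin, ymax) {
  if (is.matrix(poly)) poly <- list(poly)
  total <- 0
  for (ring in poly) {
    clipped <- clipRingRect(ring, xmin, xmax, ymin, ymax)
    if (nrow(clipped) >= 3L) total <- total + abs(ringArea(clipped))
  }
  total
}

#' Even-odd point-in-polygon test (ray casting)
#'
#' Vectorised over points; a point inside any part is inside the polygon.
#' Boundary points are resolved by the usual half-open crossing rule.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param poly list of open rings (or a single matrix).
#' @return Logical vector.
#' @export
pointsInPolygon <- function(px, py, poly) {
  if (is.matrix(poly)) poly <- list(poly)
  inside <- rep(FALSE, length(px))
  for (ring in poly) {
    x <- ring[, 1L]; y <- ring[, 2L]
    n <- length(x)
    jj <- c(n, seq_len(n - 1L))
    ins <- rep(FALSE, length(px))
    for (k in seq_len(n)) {
      xk <- x[k]; yk <- y[k]; xj <- x[jj[k]]; yj <- y[jj[k]]
      if (yk == yj) next
      crosses <- ((yk > py) != (yj > py)) &
        (px < (xj - xk) * (py - yk) / (yj - yk) + xk)
      ins <- xor(ins, crosses)
    }
    inside <- inside | ins
  }
  inside
}

# Proper-crossing test for two closed segments p1-p2 and p3-p4.
segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) -
    (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Is a ring simple (free of self-intersections)?
#'
#' Checks every pair of non-adjacent edges for a proper crossing; O(n^2),
#' adequate for county-scale rings.
#'
#' @param ring open n x 2 ring.
#' @return TRUE if no two non-adjacent edges cross.
#' @keywords internal
isSimpleRing <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (share a vertex), incl. the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segmentsCross(ring[i, ], ring[nxt[i], ], ring[j, ], ring[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Build a rectangular ring
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return An open 4 x 2 ring (counter-clockwise).
#' @export
rectRing <- function(xmin, xmax, ymin, ymax) {
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
         ncol = 2L, byrow = TRUE)
}
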