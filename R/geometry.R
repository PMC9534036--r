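# Planar geometry engine used by the whole package.
#
# A "geom" is a multipolygon: a list of rings, each ring a list(x, y) of
# open (non-repeating) vertex vectors. Even-odd fill; after any boolean
# operation outer rings carry positive signed area and holes negative, so
# geomArea() is the plain signed shoelace sum. Polylines use the same
# list(x, y) shape but are interpreted as open paths.
#
# All clipping runs at a fixed 1e-6 m resolution anchored at the origin, so
# metre- and millimetre-aligned coordinates survive the integer snapping of
# the Vatti clipper exactly. Comparisons against coverage thresholds add a
# 1e-9 guard (see .gtGuard) so snapping noise can never flip an
# exact-boundary case.

.CLIP_EPS <- 1e-6

# strict "greater than" with an absolute guard against clipper noise
.gtGuard <- function(x, threshold) x - threshold > 1e-9

# inclusive ">=" with the same guard
.geGuard <- function(x, threshold) x - threshold >= -1e-9

.emptyGeom <- function() list()

.isRing <- function(r) {
  is.list(r) && all(c("x", "y") %in% names(r)) &&
    length(r$x) == length(r$y) && length(r$x) >= 3
}

.ringArea <- function(ring) {
  x <- ring$x
  y <- ring$y
  0.5 * sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
}

geomIsEmpty <- function(g) length(g) == 0L

#' Signed area of a multipolygon
#'
#' Sum of signed shoelace areas over rings; holes (clockwise rings) count
#' negative, so the result is the net enclosed area in square map units.
#'
#' @param g a multipolygon: list of rings, each a `list(x, y)`.
#' @return numeric scalar area (m^2 for metre CRS).
#' @export
geomArea <- function(g) {
  if (geomIsEmpty(g)) return(0)
  sum(vapply(g, .ringArea, numeric(1)))
}

.geomOp <- function(a, b, op) {
  if (op %in% c("intersection", "minus") && (geomIsEmpty(a) || geomIsEmpty(b))) {
    if (op == "minus" && geomIsEmpty(b)) return(a)
    return(.emptyGeom())
  }
  if (op == "union") {
    if (geomIsEmpty(a)) return(b)
    if (geomIsEmpty(b)) return(a)
  }
  polyclip::polyclip(a, b, op = op,
                     fillA = "evenodd", fillB = "evenodd",
                     x0 = 0, y0 = 0, eps = .CLIP_EPS)
}

#' Boolean operations on multipolygons
#'
#' Union, intersection, and difference under the even-odd fill rule,
#' robust on degenerate shared-edge inputs.
#'
#' @param a,b multipolygons (lists of rings).
#' @return a multipolygon (possibly empty).
#' @rdname geomOps
#' @export
geomUnion <- function(a, b) .geomOp(a, b, "union")

#' @rdname geomOps
#' @export
geomIntersect <- function(a, b) .geomOp(a, b, "intersection")

#' @rdname geomOps
#' @export
geomDiff <- function(a, b) .geomOp(a, b, "minus")

#' Union of a list of multipolygons
#'
#' Divide-and-conquer dissolve; order-independent.
#'
#' @param geoms list of multipolygons.
#' @return a multipolygon (possibly empty).
#' @export
geomUnionAll <- function(geoms) {
  geoms <- geoms[!vapply(geoms, geomIsEmpty, logical(1))]
  n <- length(geoms)
  if (n == 0L) return(.emptyGeom())
  while (length(geoms) > 1L) {
    n <- length(geoms)
    pairs <- vector("list", ceiling(n / 2))
    for (i in seq_along(pairs)) {
      j <- 2L * i - 1L
      pairs[[i]] <- if (j + 1L <= n) geomUnion(geoms[[j]], geoms[[j + 1L]]) else geoms[[j]]
    }
    geoms <- pairs
  }
  geoms[[1L]]
}

#' Buffer open polylines
#'
#' Round joins and round end caps; the result is dissolved across input
#' paths.
#'
#' @param lines list of open paths, each a `list(x, y)`.
#' @param distance buffer distance in map units.
#' @param arctol arc approximation tolerance.
#' @return a multipolygon.
#' @export
geomBufferLines <- function(lines, distance, arctol = distance / 200) {
  polyclip::polylineoffset(lines, distance,
                           jointype = "round", endtype = "openround",
                           x0 = 0, y0 = 0, eps = .CLIP_EPS,
                           arctol = arctol)
}

#' Dilate or erode a multipolygon
#'
#' Positive `delta` dilates, negative erodes, with round joins.
#'
#' @param g multipolygon.
#' @param delta offset in map units.
#' @param arctol arc approximation tolerance.
#' @return a multipolygon (empty when eroded away).
#' @export
geomOffset <- function(g, delta, arctol = abs(delta) / 200) {
  if (geomIsEmpty(g)) return(.emptyGeom())
  polyclip::polyoffset(g, delta,
                       jointype = "round",
                       x0 = 0, y0 = 0, eps = .CLIP_EPS,
                       arctol = arctol)
}

geomBBox <- function(g) {
  if (geomIsEmpty(g)) {
    return(c(xmin = NA_real_, ymin = NA_real_, xmax = NA_real_, ymax = NA_real_))
  }
  xs <- unlist(lapply(g, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(g, `[[`, "y"), use.names = FALSE)
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Point-in-polygon membership under the even-odd rule
#'
#' Boundary points (on an edge or vertex of any ring) count as inside; this
#' is the inclusive convention used by the cell-center rasterization rule.
#'
#' @param xp,yp coordinate vectors of query points.
#' @param g multipolygon.
#' @return logical vector, one element per point.
#' @export
geomContains <- function(xp, yp, g) {
  n <- length(xp)
  if (geomIsEmpty(g) || n == 0L) return(rep(FALSE, n))
  interiorCount <- integer(n)
  onBoundary <- rep(FALSE, n)
  for (ring in g) {
    res <- sp::point.in.polygon(xp, yp, ring$x, ring$y)
    interiorCount <- interiorCount + (res == 1L)
    onBoundary <- onBoundary | res >= 2L
  }
  onBoundary | (interiorCount %% 2L == 1L)
}

#' Shared border length of two polygons
#'
#' Exact collinear overlap between boundary segments; polygons touching
#' only at a point share zero length.
#'
#' @param a,b multipolygons.
#' @param tol collinearity tolerance.
#' @return total shared length in map units.
#' @export
sharedBorderLength <- function(a, b, tol = 1e-9) {
  if (geomIsEmpty(a) || geomIsEmpty(b)) return(0)
  segA <- .geomSegments(a)
  segB <- .geomSegments(b)
  # bbox prefilter
  total <- 0
  for (i in seq_len(nrow(segA))) {
    p1 <- segA[i, 1:2]; p2 <- segA[i, 3:4]
    d <- p2 - p1
    len <- sqrt(sum(d^2))
    if (len < tol) next
    u <- d / len
    for (j in seq_len(nrow(segB))) {
      q1 <- segB[j, 1:2]; q2 <- segB[j, 3:4]
      # collinearity: both q endpoints on the infinite line through p1,p2
      c1 <- (q1[1] - p1[1]) * u[2] - (q1[2] - p1[2]) * u[1]
      c2 <- (q2[1] - p1[1]) * u[2] - (q2[2] - p1[2]) * u[1]
      scale <- max(1, len)
      if (abs(c1) > tol * scale || abs(c2) > tol * scale) next
      t1 <- (q1[1] - p1[1]) * u[1] + (q1[2] - p1[2]) * u[2]
      t2 <- (q2[1] - p1[1]) * u[1] + (q2[2] - p1[2]) * u[2]
      lo <- max(0, min(t1, t2))
      hi <- min(len, max(t1, t2))
      if (hi > lo) total <- total + (hi - lo)
    }
  }
  total
}

.geomSegments <- function(g) {
  segs <- lapply(g, function(ring) {
    n <- length(ring$x)
    cbind(ring$x, ring$y,
          c(ring$x[-1L], ring$x[1L]),
          c(ring$y[-1L], ring$y[1L]))
  })
  do.call(rbind, segs)
}

# Convenience constructors used throughout tests and fixtures.

#' Axis-aligned rectangle polygon
#'
#' @param x0,y0 lower-left corner.
#' @param width,height side lengths in map units.
#' @return a single-ring multipolygon (counter-clockwise).
#' @export
geomRect <- function(x0, y0, width, height) {
  list(list(x = c(x0, x0 + width, x0 + width, x0),
            y = c(y0, y0, y0 + height, y0 + height)))
}

# a single open path
geomPath <- function(x, y) list(x = x, y = y)
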