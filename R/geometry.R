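#' Planar geometry kernels
#'
#' Low-level, vectorized geometry used by both measurement methods: shoelace
#' polygon area, point-in-polygon tests, convex half-plane clipping, and an
#' exact (arc-aware) polygon--disc intersection area. Polygons are simple
#' closed vertex lists; the first vertex is not repeated at the end.
#'
#' @name geometry
#' @keywords internal
NULL

#' Area of a simple polygon
#'
#' Shoelace formula. The result is positive regardless of vertex orientation.
#' Self-intersecting polygons are rejected because their "area" is ill-defined
#' for defect quantification.
#'
#' @param polygon Data frame of vertices with columns `x_mm`/`y_mm` (or
#'   `x`/`y`), in order, without repeating the first vertex.
#' @param validate Check that the polygon is simple (non-self-intersecting).
#'   Disable only in hot loops on polygons already known to be simple.
#' @return Area in squared input units (a single number).
#' @examples
#' square <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' polygon_area(square)
#' @export
polygon_area <- function(polygon, validate = TRUE) {
  p <- as_xy(polygon, "polygon", min_points = 3L)
  if (validate && !polygon_is_simple(p$x, p$y)) {
    stop_glenocard("`polygon` is self-intersecting; its enclosed area is ill-defined.",
                   "glenocard_error_geometry")
  }
  abs(shoelace(p$x, p$y))
}

# Signed shoelace area (positive for counter-clockwise orientation).
shoelace <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Simple-polygon test: no two non-adjacent edges intersect. O(m^2) segment
# tests, vectorized over the pairing; fine for the vertex counts used here.
polygon_is_simple <- function(x, y, tol = 1e-12) {
  m <- length(x)
  if (m < 3) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  pairs <- utils::combn(m, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  adjacent <- (j - i == 1) | (i == 1 & j == m)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (length(i) == 0) return(TRUE)
  !any(segments_intersect(x[i], y[i], x2[i], y2[i], x[j], y[j], x2[j], y2[j], tol))
}

# Vectorized proper/improper segment intersection test.
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy, tol = 1e-12) {
  cross3 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross3(cx, cy, dx, dy, ax, ay)
  d2 <- cross3(cx, cy, dx, dy, bx, by)
  d3 <- cross3(ax, ay, bx, by, cx, cy)
  d4 <- cross3(ax, ay, bx, by, dx, dy)
  proper <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
  on_seg <- function(px, py, qx, qy, rx, ry, d) {
    abs(d) <= tol &
      rx <= pmax(px, qx) + tol & rx >= pmin(px, qx) - tol &
      ry <= pmax(py, qy) + tol & ry >= pmin(py, qy) - tol
  }
  touch <- on_seg(cx, cy, dx, dy, ax, ay, d1) | on_seg(cx, cy, dx, dy, bx, by, d2) |
    on_seg(ax, ay, bx, by, cx, cy, d3) | on_seg(ax, ay, bx, by, dx, dy, d4)
  proper | touch
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  m <- length(vx)
  inside <- logical(length(px))
  j <- m
  for (i in seq_len(m)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Exact area of the intersection of a simple polygon with a disc
#'
#' Per-edge Green's-theorem decomposition: each directed polygon edge is split
#' at its crossings with the circle; pieces inside the disc contribute a
#' signed triangle area with the centre, pieces outside contribute the signed
#' circular-sector area subtended at the centre. The sum is the exact
#' intersection area (no polygonization of the circle involved).
#'
#' @param polygon Data frame of vertices (`x_mm`/`y_mm` or `x`/`y`).
#' @param center Numeric length-2, disc centre.
#' @param radius Disc radius (> 0).
#' @param validate Check polygon simplicity (see [polygon_area()]).
#' @return Intersection area (a single non-negative number).
#' @examples
#' # half-plane x > 0 clipped to the unit disc: half the disc
#' half <- data.frame(x = c(0, 2, 2, 0), y = c(-2, -2, 2, 2))
#' circle_polygon_area(half, c(0, 0), 1) / pi
#' @export
circle_polygon_area <- function(polygon, center = c(0, 0), radius, validate = FALSE) {
  check_number(radius, "radius", positive = TRUE)
  p <- as_xy(polygon, "polygon", min_points = 3L)
  if (validate && !polygon_is_simple(p$x, p$y)) {
    stop_glenocard("`polygon` is self-intersecting.", "glenocard_error_geometry")
  }
  ax <- p$x - center[1]; ay <- p$y - center[2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- bx - ax; dy <- by - ay
  A <- dx^2 + dy^2
  B <- 2 * (ax * dx + ay * dy)
  C <- ax^2 + ay^2 - radius^2
  disc <- B^2 - 4 * A * C
  ok <- A > 0 & disc > 0
  sq <- sqrt(pmax(disc, 0))
  Asafe <- ifelse(A > 0, A, 1)
  # clamp the inside-interval [t1, t2] to the segment parameter range [0, 1]
  t1 <- ifelse(ok, pmin(pmax((-B - sq) / (2 * Asafe), 0), 1), 0)
  t2 <- ifelse(ok, pmin(pmax((-B + sq) / (2 * Asafe), 0), 1), 0)
  t2 <- pmax(t2, t1)
  p1x <- ax + t1 * dx; p1y <- ay + t1 * dy
  p2x <- ax + t2 * dx; p2y <- ay + t2 * dy
  tri <- (p1x * p2y - p1y * p2x) / 2
  sector <- function(ux, uy, vx, vy) {
    radius^2 / 2 * atan2(ux * vy - uy * vx, ux * vx + uy * vy)
  }
  total <- sum(sector(ax, ay, p1x, p1y) + tri + sector(p2x, p2y, bx, by))
  abs(total)
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# nx*x + ny*y <= c. Returns list(x, y); empty vectors if nothing remains.
# Vectorized over edges (no per-vertex R loop).
clip_halfplane <- function(x, y, nx, ny, c) {
  m <- length(x)
  if (m == 0) return(list(x = numeric(0), y = numeric(0)))
  d <- nx * x + ny * y - c
  sx <- x; sy <- y; sd <- d                      # edge start = current vertex
  ex <- c(x[-1], x[1]); ey <- c(y[-1], y[1]); ed <- c(d[-1], d[1])
  s_in <- sd <= 0; e_in <- ed <= 0
  crossed <- xor(s_in, e_in)
  t <- ifelse(crossed, sd / (sd - ed), 0)
  ix <- sx + t * (ex - sx); iy <- sy + t * (ey - sy)
  # per edge emit: intersection point (if crossing), then the end vertex (if inside)
  keep <- rbind(crossed, e_in)
  outx <- rbind(ix, ex)[keep]
  outy <- rbind(iy, ey)[keep]
  if (length(outx) < 3) return(list(x = numeric(0), y = numeric(0)))
  list(x = outx, y = outy)
}

# Clip a polygon to an axis-aligned box (four half-plane passes).
clip_box <- function(x, y, xmin, xmax, ymin, ymax) {
  p <- clip_halfplane(x, y, -1, 0, -xmin)
  p <- clip_halfplane(p$x, p$y, 1, 0, xmax)
  p <- clip_halfplane(p$x, p$y, 0, -1, -ymin)
  clip_halfplane(p$x, p$y, 0, 1, ymax)
}

#' Area fraction of a circular segment cut by a vertical chord
#'
#' For the half-plane defect `x > d` intersected with a disc of radius `r`,
#' the missing fraction of the disc is the circular-segment closed form
#' \deqn{f(d) = \frac{r^2 \arccos(d/r) - d\sqrt{r^2 - d^2}}{\pi r^2}.}
#' `chord_offset()` is the numerical inverse: the chord position producing a
#' requested fraction.
#'
#' @param d Signed chord offset from the centre, in `[-r, r]`.
#' @param r Circle radius (> 0).
#' @return `segment_fraction()`: fraction of the disc area beyond the chord,
#'   in `[0, 1]`. `chord_offset()`: the offset `d`.
#' @examples
#' segment_fraction(12.5, 25)   # chord at half the radius: ~0.1955
#' chord_offset(0.5, 25)        # chord through the centre
#' @export
segment_fraction <- function(d, r) {
  check_number(r, "r", positive = TRUE)
  check_number(d, "d", min = -r, max = r)
  (r^2 * acos(d / r) - d * sqrt(r^2 - d^2)) / (pi * r^2)
}

#' @rdname segment_fraction
#' @param fraction Target fraction of the disc area, in `[0, 1]`.
#' @export
chord_offset <- function(fraction, r) {
  check_number(r, "r", positive = TRUE)
  check_number(fraction, "fraction", min = 0, max = 1)
  if (fraction == 0) return(r)
  if (fraction == 1) return(-r)
  stats::uniroot(function(d) segment_fraction(d, r) - fraction,
                 interval = c(-r, r), tol = 1e-12 * r)$root
}
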