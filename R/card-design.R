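#' Specify a comparison card
#'
#' A comparison card is a transparent circular overlay whose disc is divided
#' into `8 * strips_per_quadrant` grid cells of exactly equal area, so that
#' the percentage of a glenoid best-fit circle missing to a bone defect can be
#' read off by counting cells. The default reproduces the clinical card: a
#' 50 mm diameter circle with 5 strips per quadrant, i.e. 40 cells of 2.5%
#' (about 49 mm\eqn{^2}) each.
#'
#' @param diameter_mm Card diameter in mm (> 0). Default 50.
#' @param strips_per_quadrant Number of equal-area vertical strips per
#'   quadrant (integer >= 1). Default 5.
#' @return An object of class `card_spec`: a list with `radius_mm`,
#'   `strips_per_quadrant` and the derived `unit_fraction = 1/(8 n)` of the
#'   disc area per cell.
#' @examples
#' card_spec()               # the 50 mm, 2.5%-per-grid card
#' card_spec(50, 1)          # degenerate 8-cell card
#' @export
card_spec <- function(diameter_mm = 50, strips_per_quadrant = 5) {
  check_number(diameter_mm, "diameter_mm", positive = TRUE)
  check_number(strips_per_quadrant, "strips_per_quadrant", min = 1)
  if (strips_per_quadrant != round(strips_per_quadrant)) {
    stop_glenocard("`strips_per_quadrant` must be a whole number.",
                   "glenocard_error_domain")
  }
  n <- as.integer(strips_per_quadrant)
  structure(
    list(radius_mm = diameter_mm / 2,
         strips_per_quadrant = n,
         unit_fraction = 1 / (8 * n)),
    class = "card_spec")
}

#' @export
print.card_spec <- function(x, ...) {
  cat(sprintf("<card_spec> diameter %g mm, %d strips/quadrant, %d cells of %.4g%% each\n",
              2 * x$radius_mm, x$strips_per_quadrant,
              8L * x$strips_per_quadrant, 100 * x$unit_fraction))
  invisible(x)
}

#' Cumulative area under a quarter-circle arc
#'
#' The area under \eqn{y = \sqrt{r^2 - x^2}} from 0 to `x`, i.e.
#' \deqn{F(x) = \frac{x\sqrt{r^2-x^2}}{2} + \frac{r^2}{2}\arcsin(x/r),}
#' the antiderivative driving the equal-area partition of the quarter disc.
#' `F` is a strictly increasing bijection from `[0, r]` onto
#' `[0, pi r^2 / 4]`.
#'
#' @param x Abscissa (vectorized), each in `[0, r]`.
#' @param r Radius (> 0).
#' @return Area(s) in squared input units.
#' @examples
#' quarter_area(25, 25)      # full quarter disc, pi * 625 / 4
#' quarter_area(1.615, 4)    # ~ 2 * pi
#' @export
quarter_area <- function(x, r) {
  check_number(r, "r", positive = TRUE)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > r)) {
    stop_glenocard("`x` must lie in [0, r].", "glenocard_error_domain")
  }
  x * sqrt(pmax(r^2 - x^2, 0)) / 2 + r^2 / 2 * asin(pmin(x / r, 1))
}

#' Equal-area cut abscissae of the quarter disc
#'
#' Solves \eqn{F(k_i) = i \, \pi r^2 / (4n)} for `i = 1, ..., n-1`, so the
#' vertical lines at the `k_i` divide the quarter disc into `n` strips of
#' equal area. The solve is done once on the unit radius (bracketed
#' root-finding on the monotone `F`, absolute area tolerance `1e-10`) and
#' scaled, so cuts are exactly scale-equivariant.
#'
#' @param r Radius (> 0).
#' @param n Strips per quadrant (integer >= 1).
#' @return Increasing numeric vector of length `n - 1`, each in `(0, r)`.
#' @examples
#' solve_cut_points(25, 5)   # 3.94, 7.99, 12.29, 17.17 (to 2 dp)
#' solve_cut_points(4, 2)    # 1.615 (to 3 dp)
#' @export
solve_cut_points <- function(r, n) {
  check_number(r, "r", positive = TRUE)
  check_number(n, "n", min = 1)
  if (n != round(n)) stop_glenocard("`n` must be a whole number.", "glenocard_error_domain")
  n <- as.integer(n)
  if (n == 1L) return(numeric(0))
  unit <- vapply(seq_len(n - 1L), function(i) {
    target <- i * pi / (4 * n)
    stats::uniroot(function(x) quarter_area(x, 1) - target,
                   interval = c(0, 1), tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
  r * unit
}

#' Area of a vertical strip below a horizontal line, under the arc
#'
#' The area of \eqn{\{(x, t) : a \le x \le b,\; 0 \le t \le
#' \min(y, \sqrt{r^2 - x^2})\}}, in closed form. With
#' \eqn{x_y = \sqrt{r^2 - y^2}}: if the arc clears the line across the whole
#' strip the region is a rectangle, `y (b - a)`; if the arc is below the line
#' everywhere the line is irrelevant, `F(b) - F(a)`; otherwise the two pieces
#' split at \eqn{x_y}. Non-decreasing in `y`, saturating at the strip area.
#'
#' @param y Height of the horizontal line (>= 0).
#' @param a,b Strip edges, `0 <= a < b <= r`.
#' @param r Radius (> 0).
#' @return Area (a single number).
#' @export
strip_area_below <- function(y, a, b, r) {
  check_number(r, "r", positive = TRUE)
  check_number(y, "y", min = 0)
  check_number(a, "a", min = 0)
  check_number(b, "b")
  if (a >= b || b > r) {
    stop_glenocard("strip edges must satisfy 0 <= a < b <= r.", "glenocard_error_domain")
  }
  x_y <- sqrt(max(r^2 - y^2, 0))
  if (y >= r || x_y >= b) {
    if (y >= r) quarter_area(b, r) - quarter_area(a, r) else y * (b - a)
  } else if (x_y <= a) {
    quarter_area(b, r) - quarter_area(a, r)
  } else {
    y * (x_y - a) + quarter_area(b, r) - quarter_area(x_y, r)
  }
}

#' Split ordinates halving each strip of the quarter disc
#'
#' For each vertical strip `[a_i, b_i]` delimited by the cut points, finds the
#' ordinate `y_i` at which the area of the strip below `y_i` equals half the
#' strip area, \eqn{\pi r^2 / (8n)}. Where the arc clears the candidate line
#' across the whole strip this is the rectangle closed form
#' \eqn{y_i = (\pi r^2 / 8n) / (b_i - a_i)}; in the outermost strip the arc
#' dips below the line and the arc-aware area condition is solved by
#' bracketed root-finding (absolute area tolerance `1e-10 r^2`).
#'
#' @param r Radius (> 0).
#' @param cuts Output of [solve_cut_points()] for the same `r`.
#' @return Numeric vector of `length(cuts) + 1` ordinates, one per strip.
#' @examples
#' solve_split_ordinates(25, solve_cut_points(25, 5))
#' @export
solve_split_ordinates <- function(r, cuts) {
  check_number(r, "r", positive = TRUE)
  if (length(cuts) > 0) {
    if (anyNA(cuts) || any(diff(c(0, cuts, r)) <= 0)) {
      stop_glenocard("`cuts` must be strictly increasing within (0, r).",
                     "glenocard_error_domain")
    }
  }
  edges <- c(0, cuts, r)
  n <- length(edges) - 1L
  half <- pi * r^2 / (8 * n)
  vapply(seq_len(n), function(i) {
    a <- edges[i]; b <- edges[i + 1]
    y_rect <- half / (b - a)
    # rectangle case: the arc clears the line over the whole strip
    if (sqrt(max(r^2 - y_rect^2, 0)) >= b) return(y_rect)
    stats::uniroot(function(y) strip_area_below(y, a, b, r) - half,
                   interval = c(0, r), tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

# Analytic boundary of one cell in quadrant 1 card coordinates.
# Returns list(x, y, arc = c(theta_start, theta_end) or NULL); the arc, when
# present, follows the last listed vertex and ends at the first.
cell_boundary_q1 <- function(a, b, y_s, r, layer) {
  h <- function(x) sqrt(pmax(r^2 - x^2, 0))
  hb <- h(b)
  if (layer == "lower") {
    if (hb >= y_s) {
      list(x = c(a, b, b, a), y = c(0, 0, y_s, y_s), arc = NULL)
    } else {
      x_c <- sqrt(r^2 - y_s^2)
      # (a,0) -> (b,0) -> (b,h(b)) -> arc -> (x_c,y_s) -> (a,y_s) -> close
      list(x = c(a, b, b), y = c(0, 0, hb),
           arc = c(atan2(hb, b), atan2(y_s, x_c)),
           x_after = c(x_c, a), y_after = c(y_s, y_s))
    }
  } else {
    if (hb >= y_s) {
      # (a,y_s) -> (b,y_s) -> (b,h(b)) -> arc -> (a,h(a)) -> close
      list(x = c(a, b, b), y = c(y_s, y_s, hb),
           arc = c(atan2(hb, b), atan2(h(a), a)),
           x_after = a, y_after = h(a))
    } else {
      x_c <- sqrt(r^2 - y_s^2)
      # (a,y_s) -> (x_c,y_s) -> arc -> (a,h(a)) -> close
      list(x = c(a, x_c), y = c(y_s, y_s),
           arc = c(atan2(y_s, x_c), atan2(h(a), a)),
           x_after = a, y_after = h(a))
    }
  }
}

# Discretize a cell boundary (quadrant-reflected) into a polygon.
# sx, sy in {+1, -1} reflect quadrant 1 into the other quadrants.
cell_polygon_xy <- function(bnd, sx, sy, r, arc_points = 64L) {
  x <- bnd$x; y <- bnd$y
  if (!is.null(bnd$arc)) {
    th <- seq(bnd$arc[1], bnd$arc[2], length.out = arc_points + 2L)
    th <- th[-c(1, length(th))]          # arc endpoints already in the list
    x <- c(x, r * cos(th), bnd$x_after)
    y <- c(y, r * sin(th), bnd$y_after)
  }
  x <- sx * x; y <- sy * y
  if (sx * sy < 0) { x <- rev(x); y <- rev(y) }   # keep orientation consistent
  list(x = x, y = y)
}

#' Convert a card cell boundary to a polygon
#'
#' Discretizes the (at most one) circular-arc piece of a cell boundary into
#' `arc_points` chord segments; straight pieces are kept exact. Intended for
#' plotting and for independent area cross-checks.
#'
#' @param card A `card_geometry` from [build_card()].
#' @param id Cell id (1-based, see `card$cells`).
#' @param arc_points Number of interior points discretizing the arc.
#' @return A tibble of vertices with columns `x_mm`, `y_mm`.
#' @export
cell_polygon <- function(card, id, arc_points = 64L) {
  stopifnot(inherits(card, "card_geometry"))
  row <- card$cells[card$cells$id == id, ]
  if (nrow(row) != 1L) stop_glenocard("unknown cell id.", "glenocard_error_domain")
  p <- cell_polygon_xy(row$boundary[[1]], row$sx, row$sy, card$spec$radius_mm,
                       arc_points = arc_points)
  tibble::tibble(x_mm = p$x, y_mm = p$y)
}

#' Build the full comparison-card geometry
#'
#' Solves the equal-area quarter partition (cut abscissae and split
#' ordinates) and mirrors it across both coordinate axes, producing the
#' `8 n` grid cells that tile the disc. Each cell is tagged with its
#' quadrant (1--4, counter-clockwise from the positive quadrant), strip index
#' (0-based, outward from the vertical axis) and layer (`"lower"`/`"upper"`,
#' below/above the strip's split ordinate), and carries an analytic boundary
#' description (line segments plus at most one circular-arc piece).
#'
#' @param spec A [card_spec()].
#' @return An object of class `card_geometry`: list with the `spec`, the
#'   solved `cuts_mm` and `split_ordinates_mm`, a `cells` tibble
#'   (`id`, `quadrant`, `strip`, `layer`, `area_mm2`, reflection signs and a
#'   `boundary` list-column) and solver `provenance`.
#' @examples
#' card <- build_card(card_spec())
#' card
#' nrow(card$cells)          # 40
#' @export
build_card <- function(spec = card_spec()) {
  if (!inherits(spec, "card_spec")) {
    stop_glenocard("`spec` must be a card_spec object.", "glenocard_error_domain")
  }
  r <- spec$radius_mm
  n <- spec$strips_per_quadrant
  cuts <- solve_cut_points(r, n)
  ords <- solve_split_ordinates(r, cuts)
  edges <- c(0, cuts, r)
  quad_signs <- list(`1` = c(1, 1), `2` = c(-1, 1), `3` = c(-1, -1), `4` = c(1, -1))
  cell_area <- pi * r^2 / (8 * n)

  grid <- tidyr::expand_grid(quadrant = 1:4, strip = seq_len(n) - 1L,
                             layer = c("lower", "upper"))
  cells <- dplyr::mutate(grid,
    id = dplyr::row_number(),
    sx = purrr::map_dbl(.data$quadrant, ~ quad_signs[[.x]][1]),
    sy = purrr::map_dbl(.data$quadrant, ~ quad_signs[[.x]][2]),
    area_mm2 = cell_area,
    boundary = purrr::map2(.data$strip, .data$layer, function(s, l) {
      cell_boundary_q1(edges[s + 1L], edges[s + 2L], ords[s + 1L], r, l)
    })
  )
  cells <- dplyr::select(cells, "id", "quadrant", "strip", "layer",
                         "area_mm2", "sx", "sy", "boundary")
  structure(
    list(spec = spec, cuts_mm = cuts, split_ordinates_mm = ords,
         cells = cells,
         provenance = list(area_tol = 1e-10 * r^2, solver = "uniroot/bisection")),
    class = "card_geometry")
}

#' @export
print.card_geometry <- function(x, ...) {
  r <- x$spec$radius_mm
  cat(sprintf("<card_geometry> diameter %g mm, %d cells of %.4g%% (%.2f mm^2) each\n",
              2 * r, nrow(x$cells), 100 * x$spec$unit_fraction,
              pi * r^2 * x$spec$unit_fraction))
  cat("  cuts (mm):           ", paste(sprintf("%.2f", x$cuts_mm), collapse = ", "), "\n")
  cat("  split ordinates (mm):", paste(sprintf("%.2f", x$split_ordinates_mm), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname build_card
#' @param x A `card_geometry`.
#' @export
#' @importFrom generics tidy
tidy.card_geometry <- function(x, ...) {
  dplyr::select(x$cells, "id", "quadrant", "strip", "layer", "area_mm2")
}
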