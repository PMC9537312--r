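#' Register a comparison card onto a fitted circle
#'
#' The card is overlaid so that its centre coincides with the centre of the
#' best-fit circle and its disc is scaled to the fitted disc ("zoom to
#' size"). The registration is a similarity transform without rotation: the
#' card's axes stay aligned with the image axes (an optional rotation is
#' exposed because angular alignment is not part of the overlay protocol; it
#' changes which cells are partial but not the error bound).
#'
#' @param card A `card_geometry`.
#' @param circle A `fit_circle`.
#' @param rotation_rad Optional rotation of the card about its centre,
#'   radians. Default 0.
#' @return An object of class `card_registration`: list with `translation`
#'   (length-2 mm), `scale` (circle radius / card radius) and `rotation_rad`.
#' @examples
#' register_card(build_card(card_spec()), as_circle(c(10, -3), 12.5))
#' @export
register_card <- function(card, circle, rotation_rad = 0) {
  stopifnot(inherits(card, "card_geometry"), inherits(circle, "fit_circle"))
  check_number(rotation_rad, "rotation_rad")
  structure(list(translation = circle$center,
                 scale = circle$radius / card$spec$radius_mm,
                 rotation_rad = rotation_rad),
            class = "card_registration")
}

#' @export
print.card_registration <- function(x, ...) {
  cat(sprintf("<card_registration> scale %.4f, translation (%.3f, %.3f) mm, rotation %.4f rad\n",
              x$scale, x$translation[1], x$translation[2], x$rotation_rad))
  invisible(x)
}

#' Read one partially filled grid with the half-grid tolerance rule
#'
#' A partial cell is read as \eqn{u/2 + \alpha} if more than half of it is
#' filled, \eqn{u/2 - \alpha} if less than half, and exactly \eqn{u/2} when
#' half-filled (within `1e-12`), where `u` is the per-grid percentage (2.5%
#' for the standard card) and \eqn{\alpha} the reading tolerance (0.5% in the
#' clinical protocol).
#'
#' @param fill_fraction Filled fraction(s) of the cell, each in open (0, 1).
#' @param unit_pct Per-grid unit percentage `u` (> 0). Default 2.5.
#' @param alpha_pct Tolerance \eqn{\alpha} in percent, in `[0, u/2]`.
#'   Default 0.5.
#' @return Read value(s) in percent, one of `u/2 - alpha`, `u/2`,
#'   `u/2 + alpha`.
#' @examples
#' grid_reading(c(0.4, 0.5, 0.6))    # 0.75, 1.25, 1.75
#' @export
grid_reading <- function(fill_fraction, unit_pct = 2.5, alpha_pct = 0.5) {
  check_number(unit_pct, "unit_pct", positive = TRUE)
  check_number(alpha_pct, "alpha_pct", min = 0)
  if (alpha_pct > unit_pct / 2) {
    stop_glenocard("`alpha_pct` must not exceed unit_pct/2 (the reading would leave [0, u]).",
                   "glenocard_error_domain")
  }
  if (!is.numeric(fill_fraction) || anyNA(fill_fraction) ||
      any(fill_fraction <= 0 | fill_fraction >= 1)) {
    stop_glenocard("`fill_fraction` must lie strictly inside (0, 1).",
                   "glenocard_error_domain")
  }
  dplyr::case_when(abs(fill_fraction - 0.5) <= 1e-12 ~ unit_pct / 2,
                   fill_fraction > 0.5 ~ unit_pct / 2 + alpha_pct,
                   TRUE ~ unit_pct / 2 - alpha_pct)
}

#' Worst-case quantization error of the reading rule
#'
#' The half-grid rule maps a true partial fill `t` (in percent of glenoid
#' area, `t` in `(0, u)`) to one of three values; its worst-case absolute
#' error per partial grid is \eqn{\max(u/2 - \alpha, \alpha)}, and errors add
#' across partial grids. With the clinical settings (`u` = 2.5, `alpha` =
#' 0.5) this limit error is 0.75% for one grid and 3% for four.
#'
#' @param n_partial Number of partially filled grids (>= 0).
#' @inheritParams grid_reading
#' @return Worst-case absolute error in percentage points.
#' @examples
#' quantization_error_bound(1)    # 0.75
#' quantization_error_bound(4)    # 3
#' @export
quantization_error_bound <- function(n_partial, unit_pct = 2.5, alpha_pct = 0.5) {
  check_number(n_partial, "n_partial", min = 0)
  check_number(unit_pct, "unit_pct", positive = TRUE)
  check_number(alpha_pct, "alpha_pct", min = 0, max = unit_pct / 2)
  n_partial * max(unit_pct / 2 - alpha_pct, alpha_pct)
}

#' Count card grids over a defect region
#'
#' Transforms the defect outline into card coordinates, computes each cell's
#' exact filled area fraction (area of cell \eqn{\cap} defect \eqn{\cap}
#' disc over the cell area, via half-plane clipping plus the arc-aware
#' polygon--disc intersection), and classifies cells as full (fraction
#' \eqn{\ge 1 - \epsilon}), empty (\eqn{\le \epsilon}) or partial
#' (\eqn{\epsilon = 10^{-6}}). Partial cells are read with the half-grid
#' tolerance rule.
#'
#' @inheritParams register_card
#' @param reg A `card_registration` from [register_card()].
#' @param defect Data frame of defect-outline vertices (`x_mm`/`y_mm`) in
#'   image coordinates, or `NULL` for no defect.
#' @param alpha_pct Reading tolerance in percent. Default 0.5.
#' @param validate Check the defect polygon for self-intersection.
#' @return An object of class `grid_readings`: list with `full_count`,
#'   `partials` (tibble: `id`, `fill_fraction`, `read_pct`), `unit_pct`,
#'   `alpha_pct`, `n_cells`.
#' @export
count_grids <- function(card, reg, defect, alpha_pct = 0.5, validate = TRUE) {
  stopifnot(inherits(card, "card_geometry"), inherits(reg, "card_registration"))
  u <- 100 * card$spec$unit_fraction
  check_number(alpha_pct, "alpha_pct", min = 0, max = u / 2)
  r <- card$spec$radius_mm
  n <- card$spec$strips_per_quadrant
  cell_area <- pi * r^2 / (8 * n)
  empty <- list(full_count = 0L,
                partials = tibble::tibble(id = integer(0),
                                          fill_fraction = numeric(0),
                                          read_pct = numeric(0)),
                unit_pct = u, alpha_pct = alpha_pct, n_cells = nrow(card$cells))
  if (is.null(defect) || nrow(defect) == 0) {
    return(structure(empty, class = "grid_readings"))
  }
  p <- as_xy(defect, "defect", min_points = 3L)
  if (validate && !polygon_is_simple(p$x, p$y)) {
    stop_glenocard("`defect` polygon is self-intersecting.", "glenocard_error_geometry")
  }
  # into card coordinates: undo translation, rotation, then scale
  dx <- p$x - reg$translation[1]
  dy <- p$y - reg$translation[2]
  if (reg$rotation_rad != 0) {
    cth <- cos(-reg$rotation_rad); sth <- sin(-reg$rotation_rad)
    dx2 <- cth * dx - sth * dy
    dy <- sth * dx + cth * dy
    dx <- dx2
  }
  dx <- dx / reg$scale; dy <- dy / reg$scale
  bbx <- range(dx); bby <- range(dy)

  edges <- c(0, card$cuts_mm, r)
  ords <- card$split_ordinates_mm
  eps <- 1e-6
  cells <- card$cells
  fills <- purrr::pmap_dbl(
    list(cells$strip, cells$layer, cells$sx, cells$sy),
    function(strip, layer, sx, sy) {
      a <- edges[strip + 1L]; b <- edges[strip + 2L]
      lo <- if (layer == "lower") 0 else ords[strip + 1L]
      hi <- if (layer == "lower") ords[strip + 1L] else r
      xmin <- min(sx * a, sx * b); xmax <- max(sx * a, sx * b)
      ymin <- min(sy * lo, sy * hi); ymax <- max(sy * lo, sy * hi)
      if (bbx[1] >= xmax || bbx[2] <= xmin || bby[1] >= ymax || bby[2] <= ymin) {
        return(0)
      }
      q <- clip_box(dx, dy, xmin, xmax, ymin, ymax)
      if (length(q$x) < 3) return(0)
      circle_polygon_area(data.frame(x = q$x, y = q$y), c(0, 0), r) / cell_area
    })
  fills <- pmin(pmax(fills, 0), 1)
  part <- fills > eps & fills < 1 - eps
  structure(list(
    full_count = sum(fills >= 1 - eps),
    partials = tibble::tibble(
      id = cells$id[part],
      fill_fraction = fills[part],
      read_pct = if (any(part)) grid_reading(fills[part], u, alpha_pct) else numeric(0)),
    unit_pct = u, alpha_pct = alpha_pct, n_cells = nrow(cells)),
    class = "grid_readings")
}

#' @export
print.grid_readings <- function(x, ...) {
  cat(sprintf("<grid_readings> %d full + %d partial of %d cells (u = %g%%, alpha = %g%%)\n",
              x$full_count, nrow(x$partials), x$n_cells, x$unit_pct, x$alpha_pct))
  invisible(x)
}

#' Defect percentage from grid readings
#'
#' `p = full_count * u + sum(partial readings)`: full grids contribute the
#' whole unit percentage, partial grids their tolerance-rule reading.
#'
#' @param readings A `grid_readings` from [count_grids()].
#' @return Defect percentage in `[0, 100]`.
#' @export
defect_percent <- function(readings) {
  stopifnot(inherits(readings, "grid_readings"))
  readings$full_count * readings$unit_pct + sum(readings$partials$read_pct)
}

#' Measure a scene with the comparison card
#'
#' Full card pipeline: fit (or accept) the best-fit circle, register the
#' card onto it, count grids over the defect and report the percentage with
#' its quantization-error bound.
#'
#' @param card A `card_geometry`.
#' @param rim Data frame of rim points, or a ready `fit_circle`.
#' @param defect Data frame of defect-outline vertices, or `NULL`.
#' @param alpha_pct Reading tolerance in percent. Default 0.5.
#' @param rotation_rad Card rotation. Default 0.
#' @return A one-row tibble: `method`, `defect_percent`, `defect_fraction`,
#'   `full_count`, `n_partial`, `error_bound_pct`, `severity`; the
#'   `grid_readings` attached as attribute `"readings"` and the circle as
#'   attribute `"circle"`.
#' @examples
#' card <- build_card(card_spec())
#' circ <- as_circle(c(0, 0), 25)
#' half <- data.frame(x_mm = c(0, 40, 40, 0), y_mm = c(-40, -40, 40, 40))
#' measure_card(card, circ, half)
#' @export
measure_card <- function(card, rim, defect, alpha_pct = 0.5, rotation_rad = 0) {
  circle <- if (inherits(rim, "fit_circle")) rim else fit_circle(rim)
  reg <- register_card(card, circle, rotation_rad)
  readings <- count_grids(card, reg, defect, alpha_pct)
  p <- defect_percent(readings)
  out <- tibble::tibble(
    method = "card",
    defect_percent = p,
    defect_fraction = p / 100,
    full_count = readings$full_count,
    n_partial = nrow(readings$partials),
    error_bound_pct = quantization_error_bound(nrow(readings$partials),
                                               readings$unit_pct, alpha_pct),
    severity = classify_severity(min(p / 100, 1)))
  attr(out, "readings") <- readings
  attr(out, "circle") <- circle
  out
}
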