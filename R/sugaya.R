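#' Sugaya best-fit-circle defect quantification
#'
#' The inferior glenoid approximates a circle en face. The Sugaya method fits
#' that circle (area \eqn{S}), takes the defect region's missing area inside
#' the circle (\eqn{A}) and reports the defect ratio \eqn{D = A/S}. The
#' defect polygon is clipped to the fitted disc before ratio-ing, so only the
#' in-disc part of a defect outline contributes.
#'
#' @param circle A `fit_circle` (from [fit_circle()] or [as_circle()]).
#' @param defect Data frame of defect-outline vertices (closed polygon,
#'   columns `x_mm`/`y_mm`), or `NULL`/zero-row for no defect.
#' @param validate Check the defect polygon for self-intersection.
#' @return A one-row tibble (the defect result): `method`, `defect_fraction`
#'   (\eqn{D \in [0,1]}), `defect_percent`, `defect_area_mm2` (\eqn{A}),
#'   `circle_area_mm2` (\eqn{S}), `severity`.
#' @examples
#' circ <- as_circle(c(0, 0), 25)
#' half <- data.frame(x_mm = c(0, 40, 40, 0), y_mm = c(-40, -40, 40, 40))
#' defect_fraction(circ, half)    # D = 0.5
#' @export
defect_fraction <- function(circle, defect, validate = TRUE) {
  if (!inherits(circle, "fit_circle")) {
    stop_glenocard("`circle` must be a fit_circle object.", "glenocard_error_domain")
  }
  S <- pi * circle$radius^2
  if (is.null(defect) || nrow(defect) == 0) {
    A <- 0
  } else {
    p <- as_xy(defect, "defect", min_points = 3L)
    if (validate && !polygon_is_simple(p$x, p$y)) {
      stop_glenocard("`defect` polygon is self-intersecting.",
                     "glenocard_error_geometry")
    }
    A <- circle_polygon_area(defect, circle$center, circle$radius)
  }
  D <- min(max(A / S, 0), 1)
  tibble::tibble(method = "sugaya",
                 defect_fraction = D,
                 defect_percent = 100 * D,
                 defect_area_mm2 = A,
                 circle_area_mm2 = S,
                 severity = classify_severity(D))
}

#' Classify defect severity
#'
#' Clinical severity classes guiding treatment: `small` (< 5%, soft-tissue
#' repair usually suffices), `medium` (5--20%), `large` (> 20%, bony
#' reconstruction considered). The boundaries 5% and 20% are assigned to
#' `medium`.
#'
#' @param D Defect fraction(s) in `[0, 1]` (vectorized).
#' @return Character vector: `"small"`, `"medium"` or `"large"`.
#' @examples
#' classify_severity(c(0.03, 0.05, 0.10, 0.25))
#' @export
classify_severity <- function(D) {
  if (!is.numeric(D) || anyNA(D) || any(D < 0 | D > 1)) {
    stop_glenocard("`D` must lie in [0, 1].", "glenocard_error_domain")
  }
  dplyr::case_when(D < 0.05 ~ "small",
                   D <= 0.20 ~ "medium",
                   TRUE ~ "large")
}

#' Measure a scene with the Sugaya method
#'
#' Convenience pipeline: fit the best-fit circle to the rim trace, then
#' compute the defect ratio of the defect outline against it.
#'
#' @param rim Data frame of rim points (`x_mm`/`y_mm`).
#' @param defect Data frame of defect-outline vertices, or `NULL`.
#' @param ... Passed to [fit_circle()].
#' @return The one-row result tibble of [defect_fraction()], with the fitted
#'   circle attached as attribute `"circle"`.
#' @export
measure_sugaya <- function(rim, defect, ...) {
  circle <- fit_circle(rim, ...)
  out <- defect_fraction(circle, defect)
  attr(out, "circle") <- circle
  out
}
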