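#' Fit a circle to glenoid rim points
#'
#' Algebraic least-squares circle fit with Taubin normalization (SVD form):
#' minimizes the sum of squared algebraic distances of
#' \eqn{A(x^2+y^2) + Bx + Cy + D} under Taubin's gradient-norm constraint,
#' which is exact on noise-free circular data and nearly unbiased for small
#' noise. The estimate is then refined by Gauss--Newton on the geometric
#' (radial) distance. This replaces the manual "draw a circle that fits the
#' rim" step with a reproducible estimator; the best-fit circle's area
#' \eqn{S = \pi \, \mathrm{radius}^2} is the denominator of the defect ratio.
#'
#' @param points Data frame of rim points, columns `x_mm`/`y_mm` (or `x`/`y`),
#'   at least 3 non-collinear points.
#' @param refine Run the geometric Gauss--Newton refinement. Default `TRUE`.
#' @return An object of class `fit_circle`: list with `center` (length-2),
#'   `radius`, `rms_residual` (root-mean-square radial misfit, mm) and `n`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' rim <- data.frame(x_mm = 1 + 5 * cos(th), y_mm = 2 + 5 * sin(th))
#' fit_circle(rim)
#' @export
fit_circle <- function(points, refine = TRUE) {
  p <- as_xy(points, "points", min_points = 3L)
  x <- p$x; y <- p$y
  xc <- x - mean(x); yc <- y - mean(y)
  # collinearity check via the smaller singular value of centred coordinates
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1)) {
    stop_glenocard("rim points are collinear; a circle cannot be fitted.",
                   "glenocard_error_degenerate")
  }
  # Taubin fit, SVD formulation on centred data
  z <- xc^2 + yc^2
  zm <- mean(z)
  Z0 <- (z - zm) / (2 * sqrt(zm))
  V <- svd(cbind(Z0, xc, yc), nu = 0)$v
  v <- V[, 3]
  A <- v[1] / (2 * sqrt(zm)); B <- v[2]; C <- v[3]; D <- -zm * A
  if (abs(A) < 1e-14) {
    stop_glenocard("degenerate (near-linear) circle fit.",
                   "glenocard_error_degenerate")
  }
  cx <- -B / (2 * A); cy <- -C / (2 * A)
  radius <- sqrt(max(B^2 + C^2 - 4 * A * D, 0)) / (2 * abs(A))
  center <- c(cx + mean(x), cy + mean(y))

  if (refine) {
    for (it in 1:20) {
      dx <- x - center[1]; dy <- y - center[2]
      di <- sqrt(dx^2 + dy^2)
      if (any(di < 1e-12)) break
      J <- cbind(-dx / di, -dy / di, rep(-1, length(x)))
      res <- di - radius
      step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
      if (is.null(step)) break
      center <- center + step[1:2]
      radius <- radius + step[3]
      if (sqrt(sum(step^2)) < 1e-12 * max(radius, 1)) break
    }
  }
  if (!is.finite(radius) || radius <= 0) {
    stop_glenocard("circle fit failed to produce a positive radius.",
                   "glenocard_error_degenerate")
  }
  dx <- x - center[1]; dy <- y - center[2]
  rms <- sqrt(mean((sqrt(dx^2 + dy^2) - radius)^2))
  structure(list(center = center, radius = radius, rms_residual = rms,
                 n = length(x)),
            class = "fit_circle")
}

#' Construct a circle object directly
#'
#' Convenience constructor for a known circle (e.g. a phantom's ground
#' truth), bypassing the fit.
#'
#' @param center Numeric length-2, centre in mm.
#' @param radius Radius in mm (> 0).
#' @return A `fit_circle` with zero residual.
#' @export
as_circle <- function(center, radius) {
  check_number(radius, "radius", positive = TRUE)
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = 0, n = 0L),
            class = "fit_circle")
}

#' @export
print.fit_circle <- function(x, ...) {
  cat(sprintf("<fit_circle> center (%.3f, %.3f) mm, radius %.3f mm, rms residual %.4g mm (n = %d)\n",
              x$center[1], x$center[2], x$radius, x$rms_residual, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.fit_circle <- function(x, ...) {
  tibble::tibble(term = c("center_x_mm", "center_y_mm", "radius_mm"),
                 estimate = c(x$center[1], x$center[2], x$radius))
}

#' @importFrom generics glance
#' @export
glance.fit_circle <- function(x, ...) {
  tibble::tibble(radius_mm = x$radius, rms_residual_mm = x$rms_residual,
                 area_mm2 = pi * x$radius^2, n_points = x$n)
}
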