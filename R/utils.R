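#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats uniroot
#' @keywords internal
"_PACKAGE"

# Structured error helper: all package errors carry class "glenocard_error"
# plus a specific subclass so callers (and the CLI) can branch on them.
stop_glenocard <- function(msg, class) {
  rlang::abort(msg, class = c(class, "glenocard_error"))
}

check_number <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_glenocard(sprintf("`%s` must be a single finite number.", name),
                   "glenocard_error_domain")
  }
  if (positive && x <= 0) {
    stop_glenocard(sprintf("`%s` must be > 0 (got %g).", name, x),
                   "glenocard_error_domain")
  }
  if (x < min || x > max) {
    stop_glenocard(sprintf("`%s` must be in [%g, %g] (got %g).", name, min, max, x),
                   "glenocard_error_domain")
  }
  invisible(x)
}

# Fold integers into a reproducible sub-stream seed < 2^31 - 1.
# Products stay below 2^53 so the arithmetic is exact in doubles.
fold_seed <- function(...) {
  parts <- c(...)
  s <- 2026
  for (p in parts) s <- (s * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(s)
}

# Validate a two-column point set (data.frame with x/y or x_mm/y_mm columns);
# returns a plain list(x =, y =) used by the geometry kernels.
as_xy <- function(points, name = "points", min_points = 1L) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!is.data.frame(points)) {
    stop_glenocard(sprintf("`%s` must be a data frame of points.", name),
                   "glenocard_error_domain")
  }
  nms <- names(points)
  xcol <- intersect(c("x_mm", "x"), nms)[1]
  ycol <- intersect(c("y_mm", "y"), nms)[1]
  if (is.na(xcol) || is.na(ycol)) {
    stop_glenocard(sprintf("`%s` must have columns x_mm/y_mm (or x/y).", name),
                   "glenocard_error_domain")
  }
  x <- as.numeric(points[[xcol]])
  y <- as.numeric(points[[ycol]])
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop_glenocard(sprintf("`%s` contains missing or non-finite coordinates.", name),
                   "glenocard_error_domain")
  }
  if (length(x) < min_points) {
    stop_glenocard(sprintf("`%s` needs at least %d points.", name, min_points),
                   "glenocard_error_domain")
  }
  list(x = x, y = y)
}
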