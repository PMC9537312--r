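# Independent oracles. These deliberately avoid the package's closed forms
# and clipping code: areas come from generic numerical quadrature
# (stats::integrate) or brute-force rasterization, and roots from a naive
# bisection, so the implementation is checked against genuinely separate
# machinery.

# Area under the quarter-circle arc from 0 to x, by numerical quadrature.
quarter_area_quad <- function(x, r) {
  if (x <= 0) return(0)
  stats::integrate(function(t) sqrt(pmax(r^2 - t^2, 0)), 0, x,
                   rel.tol = 1e-12, abs.tol = 1e-12, subdivisions = 2000L)$value
}

# Naive bisection for a monotone increasing f on [lo, hi].
bisect <- function(f, lo, hi, iter = 200L) {
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Strip area below a horizontal line, by quadrature of the integrand
# min(y, arc) over [a, b] (split at the arc crossing for accuracy).
strip_area_quad <- function(y, a, b, r) {
  f <- function(t) pmin(y, sqrt(pmax(r^2 - t^2, 0)))
  xc <- sqrt(max(r^2 - y^2, 0))
  cuts <- sort(unique(pmin(pmax(c(a, xc, b), a), b)))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    if (cuts[i + 1] > cuts[i]) {
      total <- total + stats::integrate(f, cuts[i], cuts[i + 1],
                                        rel.tol = 1e-12, abs.tol = 1e-12)$value
    }
  }
  total
}

# Area of one card cell by quadrature of its analytic bounds (independent of
# the cell-boundary construction and of any polygon clipping).
cell_area_quad <- function(card, id) {
  row <- card$cells[card$cells$id == id, ]
  edges <- c(0, card$cuts_mm, card$spec$radius_mm)
  r <- card$spec$radius_mm
  a <- edges[row$strip + 1L]; b <- edges[row$strip + 2L]
  ys <- card$split_ordinates_mm[row$strip + 1L]
  if (row$layer == "lower") {
    strip_area_quad(ys, a, b, r)
  } else {
    strip_area_quad(r, a, b, r) - strip_area_quad(ys, a, b, r)
  }
}

# Brute-force rasterization of area(polygon intersect disc), pixel centres.
raster_circle_polygon_area <- function(polygon, center, radius, px = 0.05) {
  vx <- polygon[[grep("^x", names(polygon))[1]]]
  vy <- polygon[[grep("^y", names(polygon))[1]]]
  gx <- seq(center[1] - radius, center[1] + radius, by = px)
  gy <- seq(center[2] - radius, center[2] + radius, by = px)
  g <- expand.grid(x = gx, y = gy)
  in_disc <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  g <- g[in_disc, ]
  # even-odd ray casting, independent of the package's implementation
  inside <- rep(FALSE, nrow(g))
  m <- length(vx); j <- m
  for (i in seq_len(m)) {
    crosses <- ((vy[i] > g$y) != (vy[j] > g$y)) &
      (g$x < (vx[j] - vx[i]) * (g$y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside) * px^2
}

# Brute-force worst-case error of the half-grid reading rule over true
# partial fills t in (0, u), on a fine grid.
reading_rule_max_error <- function(unit_pct, alpha_pct, n_grid = 1e5) {
  t <- seq(0, unit_pct, length.out = n_grid + 1L)
  t <- t[t > 0 & t < unit_pct]
  read <- ifelse(abs(t / unit_pct - 0.5) <= 1e-12, unit_pct / 2,
                 ifelse(t / unit_pct > 0.5, unit_pct / 2 + alpha_pct,
                        unit_pct / 2 - alpha_pct))
  max(abs(read - t))
}

# Longhand ICC(2,1) from the two-way ANOVA decomposition via stats::aov,
# independent of the package's mean-square bookkeeping.
icc21_aov <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

std_card <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- glenocard::build_card(glenocard::card_spec())
    cached
  }
})
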