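#' Synthetic glenoid phantom with known true defect fraction
#'
#' Builds a 2-D en-face phantom: a true inferior circle of radius `radius_mm`
#' centred at `center`, an anterior bone defect of known area fraction, and
#' optionally a superior "pear" extension of the outline that neither method
#' should react to. Two defect shapes are available:
#' \describe{
#'   \item{`chord`}{a straight vertical anterior cut at the offset `d`
#'     solving the circular-segment equation for `target_fraction`.}
#'   \item{`bite`}{a chord whose edge is perturbed by seeded smooth low-order
#'     modes (an irregular erosion), with the offset re-solved so the true
#'     fraction stays within `2e-3` of target.}
#' }
#' Construction validates `true_fraction` against the exact polygon--disc
#' intersection area.
#'
#' @param radius_mm True inferior-circle radius in mm (> 0). Default 25.
#' @param target_fraction Target defect fraction of the disc, in `[0, 0.5)`.
#' @param shape `"chord"` or `"bite"`.
#' @param seed Integer seed; the phantom is deterministic given
#'   (`seed`, `shape`, `target_fraction`).
#' @param center Circle centre. Default `c(0, 0)`.
#' @param bite_amplitude Relative edge-perturbation amplitude for `"bite"`
#'   (fraction of the radius). Default 0.04.
#' @param superior_extension Add a pear-shaped superior lobe (a smooth bump
#'   of height `0.6 * radius_mm` over the 60--120 degree arc) to the glenoid
#'   outline. Both methods operate on the inferior circle only, so the lobe
#'   must not change any measurement; this is verified by tests.
#' @return An object of class `glenoid_phantom`: list with `circle`
#'   (a `fit_circle`, the ground truth), `outline` (glenoid outline polygon,
#'   circle plus optional superior lobe), `defect` (vertex tibble, zero rows
#'   if no defect), `true_fraction`, `shape`, `radius_mm`, `seed`,
#'   `superior_extension`.
#' @examples
#' ph <- make_phantom(25, 0.15, "chord", seed = 1)
#' ph$true_fraction
#' @export
make_phantom <- function(radius_mm = 25, target_fraction = 0.10,
                         shape = c("chord", "bite"), seed = 1,
                         center = c(0, 0), bite_amplitude = 0.04,
                         superior_extension = FALSE) {
  shape <- match.arg(shape)
  check_number(radius_mm, "radius_mm", positive = TRUE)
  check_number(target_fraction, "target_fraction", min = 0)
  if (target_fraction >= 0.5) {
    stop_glenocard("`target_fraction` must be < 0.5 for anterior chord-type defects.",
                   "glenocard_error_domain")
  }
  r <- radius_mm
  circle <- as_circle(center, r)
  outline <- glenoid_outline(center, r, superior_extension)
  if (target_fraction == 0) {
    return(structure(list(circle = circle, outline = outline,
                          defect = tibble::tibble(x_mm = numeric(0), y_mm = numeric(0)),
                          true_fraction = 0, shape = shape,
                          radius_mm = r, seed = seed,
                          superior_extension = superior_extension),
                     class = "glenoid_phantom"))
  }
  ext <- 1.6 * r   # defect polygon extends well beyond the disc; clipped later
  if (shape == "chord") {
    d <- chord_offset(target_fraction, r)
    xs <- c(d, ext, ext, d)
    ys <- c(-ext, -ext, ext, ext)
  } else {
    d0 <- chord_offset(target_fraction, r)
    yy <- seq(-ext, ext, length.out = 41L)
    pert <- withr::with_seed(fold_seed(seed, 7001), {
      amp <- bite_amplitude * r
      a <- stats::rnorm(3, 0, amp)
      ph <- stats::runif(3, 0, 2 * pi)
      a[1] * sin(pi * yy / r + ph[1]) +
        a[2] * sin(2 * pi * yy / r + ph[2]) / 2 +
        a[3] * sin(3 * pi * yy / r + ph[3]) / 3
    })
    # re-solve the offset so the perturbed edge hits the target fraction
    frac_of <- function(offset) {
      poly <- data.frame(x = c(d0 + offset + pert, ext, ext),
                         y = c(yy, ext, -ext))
      circle_polygon_area(poly, center, r) / (pi * r^2)
    }
    off <- stats::uniroot(function(o) frac_of(o) - target_fraction,
                          interval = c(-0.5 * r, 0.5 * r), tol = 1e-10 * r)$root
    xs <- c(d0 + off + pert, ext, ext)
    ys <- c(yy, ext, -ext)
  }
  defect <- tibble::tibble(x_mm = xs + center[1], y_mm = ys + center[2])
  true_fraction <- circle_polygon_area(defect, center, r) / (pi * r^2)
  if (abs(true_fraction - target_fraction) > 2e-3) {
    stop_glenocard("phantom construction missed the target fraction.",
                   "glenocard_error_domain")
  }
  structure(list(circle = circle, outline = outline, defect = defect,
                 true_fraction = true_fraction, shape = shape,
                 radius_mm = r, seed = seed,
                 superior_extension = superior_extension),
            class = "glenoid_phantom")
}

# Glenoid outline polygon: the circle, optionally with a smooth pear-shaped
# superior lobe (height 0.6 r over the 60-120 degree arc).
glenoid_outline <- function(center, r, superior_extension, n_points = 144L) {
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  rad <- rep(r, n_points)
  if (superior_extension) {
    t <- (th - pi / 2) / (pi / 6)           # -1..1 over the 60-120 deg arc
    bump <- ifelse(abs(t) < 1, 0.6 * r * (1 + cos(pi * t)) / 2, 0)
    rad <- rad + bump
  }
  tibble::tibble(x_mm = center[1] + rad * cos(th),
                 y_mm = center[2] + rad * sin(th))
}

#' @export
print.glenoid_phantom <- function(x, ...) {
  cat(sprintf("<glenoid_phantom> r = %g mm, %s defect, true fraction %.4f (%.2f%%)\n",
              x$radius_mm, x$shape, x$true_fraction, 100 * x$true_fraction))
  invisible(x)
}

#' Observer model for simulated measurements
#'
#' Emulates an observer tracing the rim and defect outline: rim sample
#' points and defect vertices receive isotropic Gaussian jitter. Noise
#' streams are keyed by (`seed`, phantom seed, `observer`, `occasion`) so any
#' single measurement is reproducible in isolation.
#'
#' @param rim_noise_sd Rim-point jitter SD in mm (>= 0). Default 0.2.
#' @param defect_edge_noise_sd Defect-vertex jitter SD in mm (>= 0).
#'   Default 0.2.
#' @param seed Integer stream seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(rim_noise_sd = 0.2, defect_edge_noise_sd = 0.2,
                           seed = 1) {
  check_number(rim_noise_sd, "rim_noise_sd", min = 0)
  check_number(defect_edge_noise_sd, "defect_edge_noise_sd", min = 0)
  structure(list(rim_noise_sd = rim_noise_sd,
                 defect_edge_noise_sd = defect_edge_noise_sd,
                 seed = seed),
            class = "observer_model")
}

#' Simulate one observation of a phantom
#'
#' Samples at least 24 rim points on the intact part of the true circle
#' (angles inside the defect are skipped) and jitters them and the defect
#' vertices with the observer's noise SDs. With zero noise the fitted circle
#' recovers the truth exactly.
#'
#' @param phantom A `glenoid_phantom`.
#' @param model An `observer_model`.
#' @param occasion Measurement occasion index (integer), part of the noise
#'   stream key.
#' @param n_rim Number of candidate rim angles. Default 36.
#' @return List with `rim` (tibble `x_mm`, `y_mm`) and `defect`
#'   (tibble, possibly zero rows).
#' @export
observe_phantom <- function(phantom, model, occasion = 1L, n_rim = 36L) {
  stopifnot(inherits(phantom, "glenoid_phantom"), inherits(model, "observer_model"))
  r <- phantom$radius_mm
  ctr <- phantom$circle$center
  sample_rim <- function(m) {
    th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    if (isTRUE(phantom$superior_extension)) {
      # the lobe arc is not part of the inferior circle; the reader skips it
      th <- th[!(th > pi / 3 & th < 2 * pi / 3)]
    }
    px <- ctr[1] + r * cos(th)
    py <- ctr[2] + r * sin(th)
    if (nrow(phantom$defect) >= 3) {
      keep <- !points_in_polygon(px, py, phantom$defect$x_mm, phantom$defect$y_mm)
      px <- px[keep]; py <- py[keep]
    }
    list(x = px, y = py)
  }
  s <- sample_rim(n_rim)
  while (length(s$x) < 24L) {       # dense enough on the intact rim
    n_rim <- 2L * n_rim
    s <- sample_rim(n_rim)
  }
  px <- s$x; py <- s$y
  withr::with_seed(fold_seed(model$seed, phantom$seed, occasion), {
    rim <- tibble::tibble(
      x_mm = px + stats::rnorm(length(px), 0, model$rim_noise_sd),
      y_mm = py + stats::rnorm(length(py), 0, model$rim_noise_sd))
    defect <- phantom$defect
    if (nrow(defect) > 0 && model$defect_edge_noise_sd > 0) {
      defect <- tibble::tibble(
        x_mm = defect$x_mm + stats::rnorm(nrow(defect), 0, model$defect_edge_noise_sd),
        y_mm = defect$y_mm + stats::rnorm(nrow(defect), 0, model$defect_edge_noise_sd))
    }
    list(rim = rim, defect = defect)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws true defect fractions from a truncated normal (defaults: mean 0.10,
#' SD 0.08, bounds `[0, 0.45]`, matching a typical bony Bankart case mix
#' spanning the small/medium/large severity classes) and builds one phantom
#' per patient. Deterministic per seed.
#'
#' @param n_patients Number of phantoms (>= 1). Default 33.
#' @param fraction_mean,fraction_sd Mean and SD of the (untruncated) normal.
#' @param bounds Truncation bounds for the fraction. Default `c(0, 0.45)`.
#' @param radius_mm True circle radius. Default 25.
#' @param shape Defect shape, `"chord"` or `"bite"`. Default `"chord"`.
#' @param seed Integer seed.
#' @return List of `glenoid_phantom` objects, with the drawn fractions as
#'   attribute `"fractions"`.
#' @examples
#' cohort <- make_cohort(5, seed = 1)
#' sapply(cohort, function(p) p$true_fraction)
#' @export
make_cohort <- function(n_patients = 33, fraction_mean = 0.10,
                        fraction_sd = 0.08, bounds = c(0, 0.45),
                        radius_mm = 25, shape = "chord", seed = 1) {
  check_number(n_patients, "n_patients", min = 1)
  check_number(fraction_mean, "fraction_mean", min = 0)
  check_number(fraction_sd, "fraction_sd", min = 0)
  n_patients <- as.integer(n_patients)
  fractions <- withr::with_seed(fold_seed(seed, 101), {
    if (fraction_sd == 0) {
      rep(fraction_mean, n_patients)
    } else {
      out <- numeric(n_patients)
      for (i in seq_len(n_patients)) {
        repeat {
          f <- stats::rnorm(1, fraction_mean, fraction_sd)
          if (f >= bounds[1] && f <= bounds[2]) break
        }
        out[i] <- f
      }
      out
    }
  })
  phantoms <- purrr::map(seq_len(n_patients), function(i) {
    make_phantom(radius_mm, fractions[i], shape, seed = fold_seed(seed, 500, i))
  })
  attr(phantoms, "fractions") <- fractions
  phantoms
}
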