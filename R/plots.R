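#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a comparison card
#'
#' Draws the card's circle, cut chords, axes and split segments with equal
#' coordinates, as it would be printed on transparent film.
#'
#' @param object A `card_geometry`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(build_card(card_spec()))
#' @export
autoplot.card_geometry <- function(object, ...) {
  r <- object$spec$radius_mm
  th <- seq(0, 2 * pi, length.out = 361)
  circle_df <- tibble::tibble(x = r * cos(th), y = r * sin(th))
  segs <- card_segments(object)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circle_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

# all straight strokes of the card (axes, cut chords, split segments)
card_segments <- function(card) {
  r <- card$spec$radius_mm
  edges <- c(0, card$cuts_mm, r)
  rows <- list(tibble::tibble(x1 = -r, y1 = 0, x2 = r, y2 = 0),
               tibble::tibble(x1 = 0, y1 = -r, x2 = 0, y2 = r))
  for (k in card$cuts_mm) {
    h <- sqrt(r^2 - k^2)
    rows <- c(rows, list(tibble::tibble(x1 = c(k, -k), y1 = -h, x2 = c(k, -k), y2 = h)))
  }
  for (i in seq_along(card$split_ordinates_mm)) {
    y <- card$split_ordinates_mm[i]
    a <- edges[i]
    b <- min(edges[i + 1], sqrt(max(r^2 - y^2, 0)))
    for (sy in c(1, -1)) {
      rows <- c(rows, list(tibble::tibble(x1 = c(a, -a), y1 = sy * y,
                                          x2 = c(b, -b), y2 = sy * y)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Bland--Altman plot
#'
#' Scatter of per-subject differences against means with the bias line and
#' the 95% limits of agreement.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (%)", y = "Difference (%)",
                  title = sprintf("Bias %.3f, LoA [%.3f, %.3f]",
                                  object$bias, object$loa_lower, object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Plot a phantom scene
#'
#' Shows the true circle, the defect outline (clipped view window) and,
#' optionally, an observed rim trace.
#'
#' @param object A `glenoid_phantom`.
#' @param scene Optional observation (list with `rim`, `defect`) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glenoid_phantom <- function(object, scene = NULL, ...) {
  r <- object$radius_mm; ctr <- object$circle$center
  th <- seq(0, 2 * pi, length.out = 361)
  circle_df <- tibble::tibble(x = ctr[1] + r * cos(th), y = ctr[2] + r * sin(th))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circle_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal(xlim = ctr[1] + c(-1.3, 1.3) * r,
                         ylim = ctr[2] + c(-1.3, 1.3) * r) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (nrow(object$defect) >= 3) {
    p <- p + ggplot2::geom_polygon(
      data = object$defect,
      ggplot2::aes(x = .data$x_mm, y = .data$y_mm),
      fill = "grey70", alpha = 0.5)
  }
  if (!is.null(scene)) {
    p <- p + ggplot2::geom_point(
      data = scene$rim, ggplot2::aes(x = .data$x_mm, y = .data$y_mm), size = 0.8)
  }
  p
}
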