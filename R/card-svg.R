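#' Export a comparison card as an SVG overlay
#'
#' Writes an SVG 1.1 file with user units equal to millimetres (the viewBox
#' is centred on the card centre), containing the outer circle, the vertical
#' cut chords mirrored to both half-planes, the two axes, and the per-strip
#' horizontal split segments clipped to the disc. All elements are
#' stroke-only with transparent fill, so the card can be printed on
#' transparent film or overlaid on an en-face image. Output is deterministic:
#' re-exporting the same card yields a byte-identical file.
#'
#' @param card A `card_geometry` from [build_card()].
#' @param path Output file path.
#' @param stroke Stroke colour. Default `"black"`.
#' @param stroke_width Stroke width in mm. Default 0.2.
#' @param margin_mm Whitespace margin around the circle. Default 2.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".svg")
#' export_card_svg(build_card(card_spec()), f)
#' @export
export_card_svg <- function(card, path, stroke = "black", stroke_width = 0.2,
                            margin_mm = 2) {
  stopifnot(inherits(card, "card_geometry"))
  r <- card$spec$radius_mm
  fmt <- function(v) sprintf("%.6f", v)
  box <- r + margin_mm
  lines <- character(0)
  add_line <- function(x1, y1, x2, y2) {
    sprintf('  <line x1="%s" y1="%s" x2="%s" y2="%s"/>',
            fmt(x1), fmt(y1), fmt(x2), fmt(y2))
  }
  # axes (full diameters)
  lines <- c(lines, add_line(-r, 0, r, 0), add_line(0, -r, 0, r))
  # vertical cut chords, mirrored to both half-planes
  for (k in card$cuts_mm) {
    h <- sqrt(r^2 - k^2)
    lines <- c(lines, add_line(k, -h, k, h), add_line(-k, -h, -k, h))
  }
  # per-strip split segments in all four quadrants, clipped to the disc
  edges <- c(0, card$cuts_mm, r)
  for (i in seq_along(card$split_ordinates_mm)) {
    y <- card$split_ordinates_mm[i]
    a <- edges[i]
    b <- min(edges[i + 1], sqrt(max(r^2 - y^2, 0)))
    for (sy in c(1, -1)) {
      lines <- c(lines, add_line(a, sy * y, b, sy * y),
                 add_line(-a, sy * y, -b, sy * y))
    }
  }
  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%smm" height="%smm" viewBox="%s %s %s %s">'),
            fmt(2 * box), fmt(2 * box), fmt(-box), fmt(-box),
            fmt(2 * box), fmt(2 * box)),
    sprintf('<g fill="none" stroke="%s" stroke-width="%s">', stroke, fmt(stroke_width)),
    sprintf('  <circle cx="0" cy="0" r="%s"/>', fmt(r)),
    lines,
    '</g>',
    '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con, sep = "\n")
  invisible(path)
}

#' Serialize card geometry to JSON
#'
#' Dumps the solved partition (cuts, split ordinates, cell table with areas)
#' for consumption by downstream tools.
#'
#' @inheritParams export_card_svg
#' @param path Output file path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly if written to a file.
#' @export
card_to_json <- function(card, path = NULL) {
  stopifnot(inherits(card, "card_geometry"))
  obj <- list(
    diameter_mm = 2 * card$spec$radius_mm,
    strips_per_quadrant = card$spec$strips_per_quadrant,
    unit_fraction = card$spec$unit_fraction,
    cuts_mm = card$cuts_mm,
    split_ordinates_mm = card$split_ordinates_mm,
    cells = dplyr::select(card$cells, "id", "quadrant", "strip", "layer", "area_mm2"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
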