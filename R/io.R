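#' Read and write point-list CSV files
#'
#' Rim traces and defect outlines are exchanged as CSV with a header and two
#' numeric columns `x_mm`, `y_mm`. Malformed files are rejected with an error
#' naming the offending line.
#'
#' @param path CSV file path.
#' @return `read_points_csv()`: a tibble with columns `x_mm`, `y_mm`
#'   (possibly zero rows, meaning "no defect"). `write_points_csv()`: `path`,
#'   invisibly.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) {
    stop_glenocard(sprintf("file not found: %s", path), "glenocard_error_io")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("x_mm", "y_mm") %in% names(df))) {
    stop_glenocard(sprintf("%s: header must contain columns x_mm and y_mm.", path),
                   "glenocard_error_io")
  }
  x <- suppressWarnings(as.numeric(df$x_mm))
  y <- suppressWarnings(as.numeric(df$y_mm))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    stop_glenocard(sprintf("%s: non-numeric coordinates at data line %d.",
                           path, bad[1]),
                   "glenocard_error_io")
  }
  tibble::tibble(x_mm = x, y_mm = y)
}

#' @rdname read_points_csv
#' @param points Data frame with columns `x_mm`, `y_mm` (or `x`, `y`).
#' @export
write_points_csv <- function(points, path) {
  p <- as_xy(points, "points", min_points = 0L)
  readr::write_csv(tibble::tibble(x_mm = p$x, y_mm = p$y), path, progress = FALSE)
  invisible(path)
}

#' Write a measurement or study report as JSON
#'
#' Serializes one-row measurement tibbles (from [measure_card()] /
#' [measure_sugaya()] / [defect_fraction()]) or a whole `validation_study`
#' to human-readable JSON.
#'
#' @param x The object to serialize.
#' @param path Output file, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly if written to a file.
#' @export
report_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "validation_study")) {
    list(config = x$config,
         measurements = x$measurements,
         anova = x$anova,
         icc_inter = x$icc_inter,
         icc_intra = x$icc_intra,
         bland_altman = purrr::map(x$bland_altman, glance))
  } else if (is.data.frame(x)) {
    as.list(x)
  } else {
    stop_glenocard("unsupported object for report_json().", "glenocard_error_domain")
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a phantom scene to CSV point lists
#'
#' Emits the rim trace and defect outline of a phantom observation in the
#' same format [read_points_csv()] consumes.
#'
#' @param scene A list with `rim` and `defect` tibbles (from
#'   [observe_phantom()]).
#' @param rim_path,defect_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_scene_csv <- function(scene, rim_path, defect_path) {
  write_points_csv(scene$rim, rim_path)
  write_points_csv(scene$defect, defect_path)
  invisible(c(rim_path, defect_path))
}
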