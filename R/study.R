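#' Run a synthetic validation study of the card against the Sugaya method
#'
#' Reproduces the validation design on synthetic phantoms: a cohort of
#' glenoids with known defect fractions is measured with the Sugaya method
#' (one reader) and the comparison card (`n_observers` readers), on
#' `n_occasions` separate occasions, all with independent seeded observer
#' noise. The study report contains, per occasion, the across-column ANOVA
#' (Sugaya + card observers), the inter-observer ICC of the card readers,
#' and the Bland--Altman comparison of Sugaya against the mean card reading;
#' plus the intra-observer ICC of each card reader across occasions. The
#' inter-observer ICC is reported per occasion and as the mean of the
#' occasions, since "the average of the two measurements" admits both
#' readings.
#'
#' @param n_patients Cohort size. Default 33.
#' @param noise_sd_mm Observer noise SD (rim and defect edge), mm.
#'   Default 0.2.
#' @param n_observers Card readers. Default 3.
#' @param n_occasions Measurement occasions. Default 2.
#' @param card A `card_geometry`. Default: the standard 50 mm, 40-cell card.
#' @param alpha_pct Card reading tolerance. Default 0.5.
#' @param fraction_mean,fraction_sd Cohort defect-fraction distribution
#'   (truncated normal). Defaults 0.10 and 0.08.
#' @param shape Defect shape for the cohort. Default `"chord"`.
#' @param seed Integer master seed; every noise stream derives from it.
#' @return An object of class `validation_study`: list with
#'   `measurements` (long tibble: `patient`, `occasion`, `method`,
#'   `observer`, `percent`, `true_percent`), `anova` (per occasion),
#'   `icc_inter` (per occasion + mean), `icc_intra` (per card observer),
#'   `bland_altman` (list per occasion), and the configuration.
#' @examples
#' \donttest{
#' study <- run_validation_study(n_patients = 8, seed = 1)
#' study$icc_inter
#' }
#' @export
run_validation_study <- function(n_patients = 33, noise_sd_mm = 0.2,
                                 n_observers = 3, n_occasions = 2,
                                 card = build_card(card_spec()),
                                 alpha_pct = 0.5,
                                 fraction_mean = 0.10, fraction_sd = 0.08,
                                 shape = "chord", seed = 1) {
  check_number(noise_sd_mm, "noise_sd_mm", min = 0)
  cohort <- make_cohort(n_patients, fraction_mean, fraction_sd,
                        shape = shape, seed = seed)
  meas <- measure_cohort(cohort, card = card, noise_sd_mm = noise_sd_mm,
                         n_observers = n_observers, n_occasions = n_occasions,
                         alpha_pct = alpha_pct, seed = seed)

  occasions <- sort(unique(meas$occasion))
  wide_card <- function(occ) {
    w <- tidyr::pivot_wider(
      dplyr::filter(meas, .data$method == "card", .data$occasion == occ),
      id_cols = "patient", names_from = "observer", values_from = "percent")
    as.matrix(dplyr::select(w, -"patient"))
  }

  anova_tbl <- purrr::map_dfr(occasions, function(occ) {
    cols <- dplyr::filter(meas, .data$occasion == occ)
    groups <- split(cols$percent, interaction(cols$method, cols$observer, drop = TRUE))
    dplyr::mutate(compare_groups(groups), occasion = occ, .before = 1)
  })

  icc_inter <- purrr::map_dfr(occasions, function(occ) {
    dplyr::mutate(tidy(icc(wide_card(occ))), occasion = as.character(occ),
                  .before = 1)
  })
  icc_inter <- dplyr::bind_rows(
    icc_inter,
    tibble::tibble(occasion = "mean", icc = mean(icc_inter$icc),
                   grade = icc_grade(mean(icc_inter$icc)),
                   form = icc_inter$form[1],
                   n_subjects = icc_inter$n_subjects[1],
                   n_raters = icc_inter$n_raters[1]))

  icc_intra <- purrr::map_dfr(sort(unique(
    dplyr::filter(meas, .data$method == "card")$observer)), function(obs) {
      w <- tidyr::pivot_wider(
        dplyr::filter(meas, .data$method == "card", .data$observer == obs),
        id_cols = "patient", names_from = "occasion", values_from = "percent")
      dplyr::mutate(tidy(icc(as.matrix(dplyr::select(w, -"patient")))),
                    observer = obs, .before = 1)
    })

  ba <- purrr::map(occasions, function(occ) {
    sug <- dplyr::arrange(
      dplyr::filter(meas, .data$method == "sugaya", .data$occasion == occ),
      .data$patient)$percent
    card_mean <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(meas, .data$method == "card", .data$occasion == occ),
        .data$patient),
      m = mean(.data$percent))
    bland_altman(dplyr::arrange(card_mean, .data$patient)$m, sug)
  })
  names(ba) <- paste0("occasion_", occasions)

  structure(list(measurements = meas, anova = anova_tbl,
                 icc_inter = icc_inter, icc_intra = icc_intra,
                 bland_altman = ba,
                 config = list(n_patients = n_patients, noise_sd_mm = noise_sd_mm,
                               n_observers = n_observers, n_occasions = n_occasions,
                               alpha_pct = alpha_pct, fraction_mean = fraction_mean,
                               fraction_sd = fraction_sd, shape = shape,
                               seed = seed)),
            class = "validation_study")
}

#' Measure a cohort with both methods
#'
#' The simulation core of the validation study: each phantom is observed
#' independently by a Sugaya reader (observer 0) and `n_observers` card
#' readers, on each occasion, and measured with the corresponding method.
#'
#' @param cohort List of `glenoid_phantom` objects (see [make_cohort()]).
#' @inheritParams run_validation_study
#' @return Long tibble: `patient`, `occasion`, `method`, `observer`,
#'   `percent`, `true_percent`.
#' @export
measure_cohort <- function(cohort, card = build_card(card_spec()),
                           noise_sd_mm = 0.2, n_observers = 3,
                           n_occasions = 2, alpha_pct = 0.5, seed = 1) {
  grid <- tidyr::expand_grid(patient = seq_along(cohort),
                             occasion = seq_len(n_occasions),
                             observer = 0:n_observers)
  purrr::pmap_dfr(grid, function(patient, occasion, observer) {
    ph <- cohort[[patient]]
    model <- observer_model(noise_sd_mm, noise_sd_mm,
                            seed = fold_seed(seed, 900, observer))
    scene <- observe_phantom(ph, model, occasion = occasion)
    if (observer == 0L) {
      res <- measure_sugaya(scene$rim, scene$defect)
      pct <- res$defect_percent
      method <- "sugaya"
    } else {
      res <- measure_card(card, scene$rim, scene$defect, alpha_pct = alpha_pct)
      pct <- res$defect_percent
      method <- "card"
    }
    tibble::tibble(patient = patient, occasion = occasion, method = method,
                   observer = observer, percent = pct,
                   true_percent = 100 * ph$true_fraction)
  })
}

#' @export
print.validation_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<validation_study> %d phantoms, noise SD %g mm, %d card observers x %d occasions (seed %s)\n",
              cfg$n_patients, cfg$noise_sd_mm, cfg$n_observers, cfg$n_occasions,
              format(cfg$seed)))
  sum_tbl <- dplyr::summarise(
    dplyr::group_by(x$measurements, .data$occasion, .data$method, .data$observer),
    mean = mean(.data$percent), sd = stats::sd(.data$percent), .groups = "drop")
  cat("\nDefect percent, mean +/- SD per column:\n")
  print(as.data.frame(sum_tbl), digits = 4)
  cat("\nANOVA across columns (per occasion):\n")
  print(as.data.frame(x$anova), digits = 4)
  cat("\nInter-observer ICC (card):\n")
  print(as.data.frame(x$icc_inter[, c("occasion", "icc", "grade")]), digits = 4)
  cat("\nIntra-observer ICC (card):\n")
  print(as.data.frame(x$icc_intra[, c("observer", "icc", "grade")]), digits = 4)
  cat("\nBland-Altman, mean card vs Sugaya:\n")
  for (nm in names(x$bland_altman)) {
    cat(" ", nm, ": "); print(x$bland_altman[[nm]])
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.validation_study <- function(x, ...) {
  ba1 <- x$bland_altman[[1]]
  tibble::tibble(
    n_patients = x$config$n_patients,
    icc_inter_mean = x$icc_inter$icc[x$icc_inter$occasion == "mean"],
    icc_intra_min = min(x$icc_intra$icc),
    anova_p_min = min(x$anova$p_value),
    ba_bias = ba1$bias, ba_sd = ba1$sd_diff,
    ba_loa_lower = ba1$loa_lower, ba_loa_upper = ba1$loa_upper)
}
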