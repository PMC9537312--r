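#' Intraclass correlation coefficient with reliability grading
#'
#' Computes the ICC from the ANOVA mean squares of the subjects-by-raters
#' layout. The default form is two-way random effects, absolute agreement,
#' single measures — ICC(2,1):
#' \deqn{\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square over `n` subjects and `k` raters.
#' `form = "oneway"` gives ICC(1,1), pooling rater effects into error.
#' Reliability is graded `good` (> 0.75), `fair` (0.4--0.75) or `poor`
#' (< 0.4); the boundaries are assigned to `fair`.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters (or
#'   occasions) in columns; at least 2 of each, no missing cells.
#' @param form `"twoway_random_single"` (default, ICC(2,1)) or `"oneway"`
#'   (ICC(1,1)).
#' @return An object of class `icc`: list with `value`, `grade`, `form`,
#'   `n`, `k`, and the mean squares `ms` used.
#' @examples
#' m <- cbind(a = c(1, 3, 5, 7, 9, 11), b = c(2, 3, 5, 8, 9, 12))
#' icc(m)
#' @export
icc <- function(ratings, form = c("twoway_random_single", "oneway")) {
  form <- match.arg(form)
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m)) {
    stop_glenocard("`ratings` must be a complete numeric subjects-by-raters table.",
                   "glenocard_error_domain")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) {
    stop_glenocard("need at least 2 subjects and 2 raters/occasions.",
                   "glenocard_error_domain")
  }
  gm <- mean(m)
  if (sum((m - gm)^2) <= .Machine$double.eps * n * k * max(1, gm^2)) {
    stop_glenocard("all ratings are identical: total variance is zero and the ICC is undefined.",
                   "glenocard_error_degenerate")
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)
  value <- switch(form,
    twoway_random_single = (msr - mse) /
      (msr + (k - 1) * mse + k * (msc - mse) / n),
    oneway = {
      msw <- (ssc + max(sse, 0)) / (n * (k - 1))
      (msr - msw) / (msr + (k - 1) * msw)
    })
  structure(list(value = value, grade = icc_grade(value), form = form,
                 n = n, k = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc")
}

icc_grade <- function(value) {
  dplyr::case_when(value > 0.75 ~ "good",
                   value >= 0.4 ~ "fair",
                   TRUE ~ "poor")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("<icc> %s = %.4f (%s; n = %d subjects, k = %d raters)\n",
              if (x$form == "oneway") "ICC(1,1)" else "ICC(2,1)",
              x$value, x$grade, x$n, x$k))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.icc <- function(x, ...) {
  tibble::tibble(icc = x$value, grade = x$grade, form = x$form,
                 n_subjects = x$n, n_raters = x$k,
                 ms_rows = unname(x$ms["msr"]), ms_cols = unname(x$ms["msc"]),
                 ms_error = unname(x$ms["mse"]))
}

#' Bland--Altman agreement analysis
#'
#' For paired measurement series `a` and `b`, computes the differences
#' `d = a - b`, their mean (bias), sample SD, the 95% limits of agreement
#' `bias +/- 1.96 sd`, and the 95% confidence interval of the bias using the
#' t distribution, `bias +/- t(0.975, n-1) sd / sqrt(n)`.
#'
#' @param a,b Numeric vectors of equal length >= 2 (same scenes measured by
#'   two methods).
#' @param conf_mult Limit-of-agreement multiplier. Default 1.96.
#' @return An object of class `bland_altman`: list with the statistics and a
#'   `data` tibble (`mean`, `diff`) for plotting.
#' @examples
#' ba <- bland_altman(c(10, 12, 9, 15), c(10.5, 11.5, 9.2, 14.8))
#' glance(ba)
#' @export
bland_altman <- function(a, b, conf_mult = 1.96) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop_glenocard("`a` and `b` must be numeric vectors of equal length.",
                   "glenocard_error_domain")
  }
  if (length(a) < 2 || anyNA(a) || anyNA(b)) {
    stop_glenocard("need >= 2 complete pairs.", "glenocard_error_domain")
  }
  d <- a - b
  n <- length(d)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  half <- stats::qt(0.975, n - 1) * sd_diff / sqrt(n)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_lower = bias - conf_mult * sd_diff,
                 loa_upper = bias + conf_mult * sd_diff,
                 ci_bias = c(bias - half, bias + half),
                 n = n,
                 data = tibble::tibble(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4f (95%% CI %.4f to %.4f), SD %.4f, LoA %.4f to %.4f (n = %d)\n",
              x$bias, x$ci_bias[1], x$ci_bias[2], x$sd_diff,
              x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 ci_bias_lower = x$ci_bias[1], ci_bias_upper = x$ci_bias[2],
                 n = x$n)
}

#' @importFrom generics tidy
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' Across-group mean comparison
#'
#' One-way fixed-effects ANOVA across measurement groups (e.g. the Sugaya
#' column and the card observers), as used to check that observers do not
#' differ systematically. `method = "kruskal"` substitutes the rank-based
#' Kruskal--Wallis test.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values), or
#'   a data frame with columns `value` and `group`.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return A one-row tibble: `statistic`, `p_value`, `df_between`,
#'   `df_within` (ANOVA only), `method`.
#' @examples
#' compare_groups(list(rnorm(10), rnorm(10), rnorm(10)))
#' @export
compare_groups <- function(groups, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups))) {
      stop_glenocard("data frame input needs columns `value` and `group`.",
                     "glenocard_error_domain")
    }
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, 1L) < 2) ||
      any(!vapply(groups, is.numeric, TRUE))) {
    stop_glenocard("need >= 2 numeric groups with >= 2 values each.",
                   "glenocard_error_domain")
  }
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (method == "anova") {
    tab <- stats::anova(stats::lm(value ~ group))
    f <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
    if (!is.finite(f) && tab$`Sum Sq`[1] <= 1e-12 * max(1, mean(value)^2)) {
      f <- 0; p <- 1   # identical group means with zero residual variance
    }
    tibble::tibble(statistic = f, p_value = p,
                   df_between = tab$Df[1], df_within = tab$Df[2],
                   method = "anova")
  } else {
    kt <- stats::kruskal.test(value, group)
    tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                   df_between = unname(kt$parameter), df_within = NA_integer_,
                   method = "kruskal")
  }
}
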