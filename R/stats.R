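#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is run on each group; if both samples are compatible with
#' normality (p > `alpha_normality`), the groups are compared with a
#' two-sided independent-samples t-test (equal variances by default, Welch
#' available via `var_equal = FALSE`), otherwise with a two-sided
#' Mann-Whitney U test (exact enumeration for small tie-free samples, normal
#' approximation with continuity correction otherwise). No multiplicity
#' correction is applied across variables; p-values are reported raw.
#'
#' @param x,y Numeric samples (n >= 3 each).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @param variable Optional variable name carried into the output.
#' @return One-row tibble: `variable`, `n_x`, `n_y`, `mean_x`, `sd_x`,
#'   `mean_y`, `sd_y`, `normality_p_x`, `normality_p_y`, `test_used`,
#'   `statistic`, `p_value`, `significant` (p < 0.05).
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05, var_equal = TRUE,
                           variable = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    abort_lamotion("each group needs at least 3 observations", "insufficient_sample")
  }
  sw <- function(v) {
    if (stats::sd(v) == 0) return(0) # constant sample: not normal, route to rank test
    stats::shapiro.test(v)$p.value
  }
  px <- sw(x); py <- sw(y)
  if (px > alpha_normality && py > alpha_normality) {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    used <- if (var_equal) "t-test" else "welch-t-test"
  } else {
    exact <- length(x) <= 8L && length(y) <= 8L && !any(duplicated(c(x, y)))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    used <- "mann-whitney"
  }
  tibble::tibble(
    variable = variable, n_x = length(x), n_y = length(y),
    mean_x = mean(x), sd_x = stats::sd(x), mean_y = mean(y), sd_y = stats::sd(y),
    normality_p_x = px, normality_p_y = py,
    test_used = used, statistic = unname(ht$statistic), p_value = ht$p.value,
    significant = ht$p.value < 0.05
  )
}

#' Compare every variable of a tidy cohort table between two groups
#'
#' @param data Tidy cohort table with columns `subject_id`, `group`,
#'   `variable`, `value`.
#' @param control Label of the reference group (default the first level).
#' @inheritParams compare_groups
#' @return Tibble with one [compare_groups()] row per variable, plus the
#'   percent change of the comparison-group mean relative to the control
#'   mean.
#' @export
compare_cohort <- function(data, control = NULL, alpha_normality = 0.05,
                           var_equal = TRUE) {
  need <- c("subject_id", "group", "variable", "value")
  if (!all(need %in% names(data))) {
    stop_invalid_input("cohort table needs columns subject_id, group, variable, value")
  }
  groups <- unique(data$group)
  if (length(groups) != 2L) stop_invalid_input("exactly two groups required")
  if (is.null(control)) control <- groups[1L]
  case <- setdiff(groups, control)
  data |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(d, key) {
      res <- compare_groups(d$value[d$group == control], d$value[d$group == case],
                            alpha_normality, var_equal)
      res$pct_change <- percent_change(res$mean_x, res$mean_y)
      res[, setdiff(names(res), "variable")]
    }) |>
    dplyr::ungroup()
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3); pairs with missing
#'   values are dropped.
#' @param pair Optional character length-2 naming the variables.
#' @return One-row tibble: `var_x`, `var_y`, `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y, pair = c(NA_character_, NA_character_)) {
  if (length(x) != length(y)) stop_invalid_input("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort_lamotion("fewer than 3 complete pairs", "insufficient_sample")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_lamotion("zero variance: correlation undefined", "undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(var_x = pair[1L], var_y = pair[2L],
                 r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Intra-observer intraclass correlation coefficient
#'
#' Two-way single-measure ICC from the ANOVA mean squares of the n-subject
#' by 2-measurement table. The default form is ICC(2,1), absolute agreement
#' with measurements treated as random; ICC(3,1) (consistency, fixed
#' measurements) is available via `form`.
#'
#' @param rating1,rating2 Repeated measurements on the same subjects.
#' @param form `"ICC2"` (default) or `"ICC3"`.
#' @return One-row tibble: `icc`, `form`, `n`, `ms_rows`, `ms_cols`,
#'   `ms_error`.
#' @export
icc_intraobserver <- function(rating1, rating2, form = c("ICC2", "ICC3")) {
  form <- match.arg(form)
  if (length(rating1) != length(rating2)) stop_invalid_input("rating vectors must match in length")
  ok <- !is.na(rating1) & !is.na(rating2)
  r1 <- rating1[ok]; r2 <- rating2[ok]
  n <- length(r1)
  if (n < 3L) abort_lamotion("fewer than 3 paired ratings", "insufficient_sample")
  k <- 2
  m <- cbind(r1, r2)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom2 <- msr + (k - 1) * mse + k * (msc - mse) / n
  denom3 <- msr + (k - 1) * mse
  if (denom2 <= 0 || denom3 <= 0 || (msr == 0 && mse == 0)) {
    abort_lamotion("degenerate variance structure: ICC undefined", "undefined_icc")
  }
  icc <- switch(form, ICC2 = (msr - mse) / denom2, ICC3 = (msr - mse) / denom3)
  tibble::tibble(icc = icc, form = form, n = n,
                 ms_rows = msr, ms_cols = msc, ms_error = mse)
}

#' Percent change of a comparison value relative to a reference
#'
#' `(comparison - reference) / reference * 100`; positive values are
#' increases relative to the reference.
#'
#' @param reference,comparison Numeric (vectorised); `reference` must be
#'   non-zero.
#' @return Percent change.
#' @examples
#' percent_change(176.9, 298.9) # +69%
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference == 0)) stop_invalid_input("reference value must be non-zero")
  (comparison - reference) / reference * 100
}
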