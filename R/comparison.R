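#' Case-wise average pelvic tilt
#'
#' Averages each parameter variant over the included annotators of each
#' image. With an exclusion mask, measurements matching the mask's
#' `(image_id, annotator_id, definition, method)` rows are removed first;
#' images losing all annotators for a variant simply have no row for that
#' variant and are later dropped pairwise by [compare_datasets()].
#'
#' @param measurements A measurement table (`image_id`, `annotator_id`,
#'   `definition`, `method`, `angle_deg`), e.g. from [compute_pt_all()].
#' @param mask Optional exclusion mask from [exclusion_mask()]; `NULL` means
#'   no exclusions.
#' @return A tibble with columns `parameter` (`PT_m_cal`, `PT_m_est`,
#'   `PT_a`), `image_id`, `angle_deg` (case mean), `n_annotators`.
#' @export
case_average <- function(measurements, mask = NULL) {
  if (nrow(measurements) == 0) stop("no measurements supplied", call. = FALSE)
  m <- measurements
  if (!is.null(mask) && nrow(mask) > 0) {
    m <- dplyr::anti_join(
      m, mask[, c("image_id", "annotator_id", "definition", "method")],
      by = c("image_id", "annotator_id", "definition", "method"))
  }
  m$parameter <- parameter_label(m$definition, m$method)
  dplyr::summarise(
    dplyr::group_by(m, .data$parameter, .data$image_id),
    angle_deg = mean(.data$angle_deg),
    n_annotators = dplyr::n(),
    .groups = "drop")
}

#' Pearson correlation strength band
#'
#' Maps a correlation coefficient onto the qualitative scale used to read
#' the full-versus-adequate agreement: poor (r < 0.3), fair (0.3-0.5),
#' moderate (0.5-0.6), moderate strong (0.6-0.8), very strong (r > 0.8).
#' Values exactly on a cut-point fall in the lower band.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
correlation_band <- function(r) {
  stopifnot(all(r >= -1 & r <= 1))
  dplyr::case_when(
    r <= 0.3 ~ "poor",
    r <= 0.5 ~ "fair",
    r <= 0.6 ~ "moderate",
    r <= 0.8 ~ "moderate_strong",
    TRUE ~ "very_strong")
}

compare_one <- function(full, adequate, ci_method) {
  d <- full - adequate
  n <- length(d)
  mean_d <- mean(d)
  sd_d <- stats::sd(d)
  r <- if (sd_d == 0 || stats::sd(full) == 0 || stats::sd(adequate) == 0) {
    if (all(d == d[1])) 1 else stats::cor(full, adequate)
  } else {
    stats::cor(full, adequate)
  }
  if (sd_d == 0) {
    p <- 1
    ci <- c(mean_d, mean_d)
  } else {
    p <- stats::t.test(full, adequate, paired = TRUE)$p.value
    ci <- if (ci_method == "loa") {
      mean_d + c(-1.96, 1.96) * sd_d
    } else {
      mean_d + c(-1.96, 1.96) * sd_d / sqrt(n)
    }
  }
  tibble::tibble(
    n_cases = n, pearson_r = r, r_band = correlation_band(r),
    mean_abs_diff = mean(abs(d)), max_abs_diff = max(abs(d)),
    ci_low = ci[1], ci_high = ci[2], t_p_value = p)
}

#' Compare the full and the adequate measurement datasets
#'
#' For each parameter variant, pairs the case means of the full dataset with
#' those of the adequate dataset (images with no adequate annotation left
#' for a variant are dropped from both series) and reports Pearson's r with
#' its strength band, the mean and maximum absolute paired difference, a 95%
#' interval on the paired differences, and the two-sided paired t-test
#' p-value.
#'
#' The default interval is the Bland-Altman limits of agreement,
#' mean difference +/- 1.96 x SD of the differences, which describes the
#' spread of per-case discrepancies; `ci_method = "sem"` gives the
#' standard-error-based 95% CI of the mean difference instead.
#'
#' When the two series are identical the paired t statistic is undefined;
#' the p-value is reported as 1 and the interval collapses to the (zero)
#' mean difference.
#'
#' @param full,adequate Case-mean tables from [case_average()].
#' @param ci_method `"loa"` (limits of agreement, default) or `"sem"`.
#' @return A tibble with one row per parameter: `parameter`, `n_cases`,
#'   `pearson_r`, `r_band`, `mean_abs_diff`, `max_abs_diff`, `ci_low`,
#'   `ci_high`, `t_p_value`.
#' @export
compare_datasets <- function(full, adequate, ci_method = c("loa", "sem")) {
  ci_method <- match.arg(ci_method)
  paired <- dplyr::inner_join(full, adequate, by = c("parameter", "image_id"),
                              suffix = c("_full", "_adequate"))
  out <- dplyr::group_modify(
    dplyr::group_by(paired, .data$parameter),
    function(g, key) {
      if (nrow(g) < 3) {
        stop(sprintf("insufficient data: parameter %s has %d paired case(s), need >= 3",
                     key$parameter, nrow(g)), call. = FALSE)
      }
      compare_one(g$angle_deg_full, g$angle_deg_adequate, ci_method)
    })
  dplyr::ungroup(out)
}

#' Intraclass correlation against a reference series
#'
#' Agreement between two aligned measurement series (e.g. the study's
#' case-mean mechanical pelvic tilt versus the values reported by the
#' radiographic technician). The default form is ICC(2,1): two-way random
#' effects, absolute agreement, single measurement, computed from the
#' two-way ANOVA mean squares; `"icc3_1"` gives the consistency form, which
#' ignores a systematic offset between the series. Values above 0.9 are read
#' as excellent agreement.
#'
#' @param series_a,series_b Aligned numeric vectors, one value per image.
#' @param form `"icc2_1"` (absolute agreement, default) or `"icc3_1"`
#'   (consistency).
#' @return The ICC as a single number.
#' @export
icc_agreement <- function(series_a, series_b, form = c("icc2_1", "icc3_1")) {
  form <- match.arg(form)
  if (length(series_a) != length(series_b)) {
    stop("series must be aligned (equal length)", call. = FALSE)
  }
  n <- length(series_a)
  if (n < 3) stop("insufficient data: need >= 3 aligned pairs", call. = FALSE)
  x <- cbind(series_a, series_b)
  k <- ncol(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  mse <- sum((x - outer(row_means, rep(1, k)) -
              outer(rep(1, n), col_means) + grand)^2) / ((n - 1) * (k - 1))
  if (form == "icc2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}
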