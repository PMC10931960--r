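# Naive reimplementations of the comparison statistics, used as independent
# oracles. Each is written from the defining formula with explicit sums.

naive_pearson <- function(x, y) {
  cx <- x - sum(x) / length(x)
  cy <- y - sum(y) / length(y)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

naive_mean_abs_diff <- function(x, y) sum(abs(x - y)) / length(x)

naive_max_abs_diff <- function(x, y) max(abs(x - y))

naive_loa <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  c(m - 1.96 * s, m + 1.96 * s)
}

naive_paired_t_p <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

# ICC via the two-way ANOVA table fitted by lm(), an independent route to the
# mean squares used by icc_agreement().
anova_icc <- function(a, b, form = "icc2_1") {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- stats::anova(stats::lm(y ~ subject + rater, data = df))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  if (form == "icc2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# Minimal single-annotator annotation table covering every landmark, with
# hand-placed coordinates (femoral contours on circles centred (100, 300) and
# (140, 300), radius 25).
toy_landmarks <- function(image_id = "img1", annotator_id = "ann1") {
  circle <- function(cx, cy, r, deg) {
    cbind(cx + r * cos(deg * pi / 180), cy + r * sin(deg * pi / 180))
  }
  c1 <- circle(100, 300, 25, c(0, 120, 240))
  c2 <- circle(140, 300, 25, c(10, 130, 250))
  tibble::tibble(
    image_id = image_id, annotator_id = annotator_id,
    landmark = c("asis_centre", "pubic_tubercle",
                 rep("femoral_head_1_contour", 3),
                 rep("femoral_head_2_contour", 3),
                 "femoral_head_centre_est",
                 "sacral_plate_anterior", "sacral_plate_posterior",
                 "sacral_midpoint_est"),
    method = c("estimation", "estimation", rep("calculation", 6),
               "estimation", "calculation", "calculation", "estimation"),
    point_index = c(0L, 0L, 0:2, 0:2, 0L, 0L, 0L, 0L),
    x = c(110, 125, c1[, 1], c2[, 1], 120, 160, 200, 180),
    y = c(180, 360, c1[, 2], c2[, 2], 300, 160, 140, 150))
}

# Rating-table builder: takes a data frame of flags (image_id, assessor_id,
# landmark, annotator_id, reason) and fills in all-satisfactory rows so every
# (image, assessor, review landmark) is covered.
build_ratings <- function(flags, image_ids,
                          assessor_ids = paste0("assessor", 1:3)) {
  grid <- tidyr::expand_grid(image_id = image_ids,
                             assessor_id = assessor_ids,
                             landmark = pt_review_landmarks())
  if (nrow(flags) > 0) {
    flags <- tibble::as_tibble(flags)
    ok <- dplyr::anti_join(
      grid, dplyr::distinct(flags, image_id, assessor_id, landmark),
      by = c("image_id", "assessor_id", "landmark"))
  } else {
    ok <- grid
  }
  ok$annotator_id <- NA_character_
  ok$reason <- NA_character_
  dplyr::bind_rows(flags, ok)
}
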