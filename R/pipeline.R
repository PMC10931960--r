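as_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Simulate a study and write its files
#'
#' Runs the synthetic generator end to end and writes `landmarks.csv`,
#' `ratings.csv` and `truth.csv` into `out_dir` in the pipeline's standard
#' schemas.
#'
#' @inheritParams simulate_study
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(out_dir, n_images = 115,
                         template = pelvis_template(),
                         noise = noise_model(), assessors = assessor_model(),
                         n_annotators = 5, n_assessors = 3,
                         pt_jitter_deg = 12, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(n_images, template, noise, assessors, n_annotators,
                        n_assessors, pt_jitter_deg, seed)
  paths <- list(landmarks = file.path(out_dir, "landmarks.csv"),
                ratings = file.path(out_dir, "ratings.csv"),
                truth = file.path(out_dir, "truth.csv"))
  write_landmarks(sim$landmarks, paths$landmarks)
  write_ratings(sim$ratings, paths$ratings)
  readr::write_csv(sim$truth, paths$truth, progress = FALSE)
  invisible(paths)
}

#' Compute all pelvic-tilt measurements from a landmarks file
#'
#' @param landmarks Landmark table or path to a landmarks CSV.
#' @inheritParams compute_pt
#' @param out Optional path for the measurements CSV (`image_id`,
#'   `annotator_id`, `definition`, `method`, `angle_deg`).
#' @return The measurements tibble.
#' @export
run_compute <- function(landmarks, posterior_direction = c("neg_x", "pos_x"),
                        out = NULL) {
  posterior_direction <- match.arg(posterior_direction)
  lm <- as_table(landmarks, read_landmarks)
  meas <- compute_pt_all(lm, posterior_direction)
  if (!is.null(out)) readr::write_csv(meas, out, progress = FALSE)
  meas
}

#' Resolve the review and build the three report tables
#'
#' Resolves the assessor ratings by majority rule and produces the
#' landmark-wise and reason-wise inadequacy tables plus the parameter-wise
#' full-versus-adequate comparison. When a reference series is supplied
#' (`image_id`, `pt_m_deg`, e.g. technician software measurements), the ICC
#' of each mechanical-tilt variant's full-dataset case means against it is
#' reported as well.
#'
#' @param measurements Measurement table or CSV path.
#' @param ratings Rating table or CSV path.
#' @param n_images Number of study images; defaults to the number of
#'   distinct images in `measurements`.
#' @param k Majority threshold passed to [resolve_adequacy()].
#' @param n_assessors Assessor coverage passed to [resolve_adequacy()].
#' @inheritParams compare_datasets
#' @param reference Optional reference table or CSV path (`image_id`,
#'   `pt_m_deg`).
#' @param icc_form ICC form passed to [icc_agreement()].
#' @param out_dir Optional directory for `landmark_wise.csv`,
#'   `reason_wise.csv`, `comparison.csv` (angles and r rounded to two
#'   decimals, matching the report print convention) and `icc.csv`.
#' @return A list with `resolutions`, `landmark_wise`, `reason_wise`,
#'   `comparison` (full precision) and `icc` (or `NULL`).
#' @export
run_report <- function(measurements, ratings, n_images = NULL, k = 2,
                       n_assessors = 3, ci_method = c("loa", "sem"),
                       reference = NULL, icc_form = c("icc2_1", "icc3_1"),
                       out_dir = NULL) {
  ci_method <- match.arg(ci_method)
  icc_form <- match.arg(icc_form)
  meas <- as_table(measurements, function(p)
    readr::read_csv(p, col_types = readr::cols(
      image_id = readr::col_character(),
      annotator_id = readr::col_character(),
      definition = readr::col_character(),
      method = readr::col_character(),
      angle_deg = readr::col_double()), progress = FALSE))
  rat <- as_table(ratings, read_ratings)
  if (is.null(n_images)) n_images <- dplyr::n_distinct(meas$image_id)

  res <- resolve_adequacy(rat, k = k, n_assessors = n_assessors)
  t1 <- tabulate_landmark_wise(res, n_images)
  t2 <- tabulate_reason_wise(res, n_images)
  mask <- exclusion_mask(res)
  full <- case_average(meas)
  adequate <- case_average(meas, mask)
  t3 <- compare_datasets(full, adequate, ci_method)

  icc <- NULL
  if (!is.null(reference)) {
    ref <- as_table(reference, function(p)
      readr::read_csv(p, col_types = readr::cols(
        image_id = readr::col_character(),
        pt_m_deg = readr::col_double()), progress = FALSE))
    icc <- purrr::map_dfr(c("PT_m_cal", "PT_m_est"), function(par) {
      series <- dplyr::inner_join(full[full$parameter == par, ], ref,
                                  by = "image_id")
      tibble::tibble(parameter = par, n = nrow(series),
                     icc = icc_agreement(series$angle_deg, series$pt_m_deg,
                                         icc_form))
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(t1, file.path(out_dir, "landmark_wise.csv"),
                     progress = FALSE)
    readr::write_csv(t2, file.path(out_dir, "reason_wise.csv"),
                     progress = FALSE)
    t3_print <- dplyr::mutate(t3, dplyr::across(
      c("pearson_r", "mean_abs_diff", "max_abs_diff", "ci_low", "ci_high",
        "t_p_value"), function(v) round(v, 2)))
    readr::write_csv(t3_print, file.path(out_dir, "comparison.csv"),
                     progress = FALSE)
    if (!is.null(icc)) {
      readr::write_csv(icc, file.path(out_dir, "icc.csv"), progress = FALSE)
    }
  }
  list(resolutions = res, landmark_wise = t1, reason_wise = t2,
       comparison = t3, icc = icc)
}
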