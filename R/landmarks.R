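#' @importFrom rlang .data
NULL

#' Landmark vocabulary
#'
#' The annotation schema distinguishes the raw landmarks placed by annotators
#' from the review-level landmarks that assessors rate. Raw landmarks carry a
#' fixed number of points: each femoral-head contour carries three points, all
#' other landmarks carry one. The calculation method annotates bone contours
#' (femoral-head contours, sacral-endplate ends) from which the measurement
#' points are derived geometrically; the estimation method annotates the
#' presumed measurement point directly. The ASIS centre and pubic tubercle,
#' used only by the anatomical pelvic-tilt definition, are single clicked
#' points and are filed under the estimation method.
#'
#' @format `pt_landmarks()` returns a tibble with one row per raw landmark and
#'   columns `landmark`, `method` and `n_points`; `pt_review_landmarks()` and
#'   `pt_flag_reasons()` return character vectors.
#' @export
pt_landmarks <- function() {
  tibble::tibble(
    landmark = c("asis_centre", "pubic_tubercle",
                 "femoral_head_1_contour", "femoral_head_2_contour",
                 "femoral_head_centre_est",
                 "sacral_plate_anterior", "sacral_plate_posterior",
                 "sacral_midpoint_est"),
    method = c("estimation", "estimation",
               "calculation", "calculation",
               "estimation",
               "calculation", "calculation",
               "estimation"),
    n_points = c(1L, 1L, 3L, 3L, 1L, 1L, 1L, 1L)
  )
}

#' @rdname pt_landmarks
#' @export
pt_review_landmarks <- function() {
  c("asis_centre", "pubic_tubercle",
    "femoral_head_centre_cal", "femoral_head_centre_est",
    "sacral_midpoint_cal", "sacral_midpoint_est")
}

#' @rdname pt_landmarks
#' @export
pt_flag_reasons <- function() {
  c("bad_quality", "anomaly", "outlier", "other")
}

landmark_cols <- c("image_id", "annotator_id", "method", "landmark",
                   "point_index", "x", "y")

#' Validate a landmark annotation table
#'
#' Checks the long-format annotation table against the schema: required
#' columns, known landmark and method names, finite coordinates, consistency
#' of each landmark's method, uniqueness of `(image, annotator, method,
#' landmark, point_index)`, and the per-landmark point counts (three points
#' per femoral-head contour, one point everywhere else).
#'
#' @param landmarks A data frame with columns `image_id`, `annotator_id`,
#'   `method`, `landmark`, `point_index` (0-based), `x`, `y`.
#' @return The validated table as a tibble, invisibly sorted by the schema
#'   key.
#' @export
validate_landmarks <- function(landmarks) {
  missing <- setdiff(landmark_cols, names(landmarks))
  if (length(missing) > 0) {
    stop("landmark table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lm <- tibble::as_tibble(landmarks)[landmark_cols]
  lm$image_id <- as.character(lm$image_id)
  lm$annotator_id <- as.character(lm$annotator_id)
  lm$point_index <- as.integer(lm$point_index)

  vocab <- pt_landmarks()
  unknown <- setdiff(unique(lm$landmark), vocab$landmark)
  if (length(unknown) > 0) {
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(lm$method %in% c("calculation", "estimation"))) {
    stop("method must be 'calculation' or 'estimation'", call. = FALSE)
  }
  if (!all(is.finite(lm$x)) || !all(is.finite(lm$y))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  expected_method <- stats::setNames(vocab$method, vocab$landmark)
  bad_method <- lm$method != expected_method[lm$landmark]
  if (any(bad_method)) {
    b <- lm[which(bad_method)[1], ]
    stop(sprintf("landmark '%s' must carry method '%s' (image %s, annotator %s)",
                 b$landmark, expected_method[[b$landmark]], b$image_id,
                 b$annotator_id), call. = FALSE)
  }

  counts <- dplyr::count(lm, .data$image_id, .data$annotator_id,
                         .data$landmark)
  expected_n <- stats::setNames(vocab$n_points, vocab$landmark)
  bad <- counts$n != expected_n[counts$landmark]
  if (any(bad)) {
    b <- counts[which(bad)[1], ]
    stop(sprintf(
      "landmark '%s' has %d point(s), expected %d (image %s, annotator %s)",
      b$landmark, b$n, expected_n[[b$landmark]], b$image_id, b$annotator_id),
      call. = FALSE)
  }
  idx <- dplyr::summarise(
    dplyr::group_by(lm, .data$image_id, .data$annotator_id, .data$landmark),
    ok = identical(sort(.data$point_index), seq_len(dplyr::n()) - 1L),
    .groups = "drop")
  if (!all(idx$ok)) {
    b <- idx[which(!idx$ok)[1], ]
    stop(sprintf(
      "point_index for landmark '%s' must be 0..n-1 without repeats (image %s, annotator %s)",
      b$landmark, b$image_id, b$annotator_id), call. = FALSE)
  }
  dplyr::arrange(lm, .data$image_id, .data$annotator_id, .data$method,
                 .data$landmark, .data$point_index)
}

#' Read and write landmark annotation tables
#'
#' Landmark files hold one row per annotated point with columns `image_id`,
#' `annotator_id`, `method`, `landmark`, `point_index` (0-based), `x`, `y`
#' (pixel coordinates, origin top-left, y increasing downward). The CSV
#' dialect is comma-separated UTF-8 with a header; the JSON dialect is an
#' array of row objects. Rows with unknown landmark names are dropped with a
#' warning before validation. Writing sorts rows by `(image_id, annotator_id,
#' method, landmark, point_index)` so output is deterministic, and a
#' write/read round trip reproduces coordinates exactly.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"json"`.
#' @param landmarks A validated landmark table (see [validate_landmarks()]).
#' @return `read_landmarks()` returns a validated tibble; `write_landmarks()`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    lm <- readr::read_csv(
      path,
      col_types = readr::cols(
        image_id = readr::col_character(),
        annotator_id = readr::col_character(),
        method = readr::col_character(),
        landmark = readr::col_character(),
        point_index = readr::col_integer(),
        x = readr::col_double(),
        y = readr::col_double()),
      progress = FALSE)
  } else {
    lm <- tibble::as_tibble(jsonlite::fromJSON(path))
    if (nrow(lm) == 0) lm <- empty_landmarks()
  }
  missing <- setdiff(landmark_cols, names(lm))
  if (length(missing) > 0) {
    stop("landmark file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- !(lm$landmark %in% pt_landmarks()$landmark)
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " row(s) with unknown landmark name(s): ",
            paste(unique(lm$landmark[unknown]), collapse = ", "),
            call. = FALSE)
    lm <- lm[!unknown, ]
  }
  validate_landmarks(lm)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  lm <- if (nrow(landmarks) > 0) validate_landmarks(landmarks) else
    empty_landmarks()
  if (dialect == "csv") {
    readr::write_csv(lm, path, progress = FALSE)
  } else {
    jsonlite::write_json(lm, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

empty_landmarks <- function() {
  tibble::tibble(image_id = character(), annotator_id = character(),
                 method = character(), landmark = character(),
                 point_index = integer(), x = double(), y = double())
}
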