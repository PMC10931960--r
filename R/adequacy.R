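rating_cols <- c("image_id", "assessor_id", "landmark", "annotator_id",
                 "reason")

#' Read, write and validate assessor rating tables
#'
#' Ratings record the secondary adequacy review: for each (image, assessor,
#' review-level landmark) either one all-satisfactory row (`annotator_id` and
#' `reason` empty) or one row per flagged annotation giving the flagged
#' annotator and the reason (`bad_quality`, `anomaly`, `outlier`, `other`).
#'
#' @param path File path.
#' @param dialect `"csv"` or `"json"`.
#' @param ratings A rating table with columns `image_id`, `assessor_id`,
#'   `landmark`, `annotator_id`, `reason`.
#' @return `read_ratings()` returns a validated tibble; `write_ratings()`
#'   returns `path` invisibly.
#' @export
read_ratings <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    r <- readr::read_csv(
      path,
      col_types = readr::cols(
        image_id = readr::col_character(),
        assessor_id = readr::col_character(),
        landmark = readr::col_character(),
        annotator_id = readr::col_character(),
        reason = readr::col_character()),
      progress = FALSE)
  } else {
    r <- tibble::as_tibble(jsonlite::fromJSON(path))
    if (nrow(r) == 0) r <- empty_ratings()
  }
  validate_ratings(r)
}

#' @rdname read_ratings
#' @export
write_ratings <- function(ratings, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  r <- if (nrow(ratings) > 0) validate_ratings(ratings) else empty_ratings()
  if (dialect == "csv") {
    readr::write_csv(r, path, progress = FALSE, na = "")
  } else {
    jsonlite::write_json(r, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' @rdname read_ratings
#' @export
validate_ratings <- function(ratings) {
  missing <- setdiff(rating_cols, names(ratings))
  if (length(missing) > 0) {
    stop("rating table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r <- tibble::as_tibble(ratings)[rating_cols]
  r$image_id <- as.character(r$image_id)
  r$assessor_id <- as.character(r$assessor_id)
  r$annotator_id <- as.character(r$annotator_id)
  r$annotator_id[!is.na(r$annotator_id) & r$annotator_id == ""] <- NA_character_
  r$reason[!is.na(r$reason) & r$reason == ""] <- NA_character_
  unknown <- setdiff(unique(r$landmark), pt_review_landmarks())
  if (length(unknown) > 0) {
    stop("unknown review landmark(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  flagged <- !is.na(r$annotator_id)
  if (any(is.na(r$reason[flagged]))) {
    stop("flag rows must carry a reason", call. = FALSE)
  }
  if (any(!is.na(r$reason[!flagged]))) {
    stop("all-satisfactory rows must not carry a reason", call. = FALSE)
  }
  bad_reason <- setdiff(unique(r$reason[flagged]), pt_flag_reasons())
  if (length(bad_reason) > 0) {
    stop("unknown flag reason(s): ", paste(bad_reason, collapse = ", "),
         call. = FALSE)
  }
  dup <- dplyr::count(r[flagged, ], .data$image_id, .data$assessor_id,
                      .data$landmark, .data$annotator_id)
  if (any(dup$n > 1)) {
    b <- dup[which(dup$n > 1)[1], ]
    stop(sprintf("assessor %s flags annotator %s more than once (image %s, landmark %s)",
                 b$assessor_id, b$annotator_id, b$image_id, b$landmark),
         call. = FALSE)
  }
  mixed <- dplyr::summarise(
    dplyr::group_by(r, .data$image_id, .data$assessor_id, .data$landmark),
    ok = all(is.na(.data$annotator_id)) || all(!is.na(.data$annotator_id)),
    .groups = "drop")
  if (!all(mixed$ok)) {
    b <- mixed[which(!mixed$ok)[1], ]
    stop(sprintf("rating for image %s, assessor %s, landmark %s mixes all-satisfactory and flag rows",
                 b$image_id, b$assessor_id, b$landmark), call. = FALSE)
  }
  dplyr::arrange(r, .data$image_id, .data$assessor_id, .data$landmark,
                 .data$annotator_id)
}

empty_ratings <- function() {
  tibble::tibble(image_id = character(), assessor_id = character(),
                 landmark = character(), annotator_id = character(),
                 reason = character())
}

#' Resolve assessor ratings by majority rule
#'
#' Applies the majority ("two or more assessors") rule to the three review
#' clauses independently for each (image, review landmark):
#'
#' * landmark-wise: the landmark is inadequate when at least `k` assessors
#'   flagged at least one of its annotations (not necessarily the same one);
#' * reason-wise: a reason enters the majority set when at least `k`
#'   assessors cited it for this landmark, regardless of which annotator each
#'   attached it to;
#' * annotation-wise: an annotator's annotation is excluded when at least `k`
#'   assessors flagged that same annotator, regardless of reason agreement.
#'
#' With the study's three assessors and the default `k = 2` no ties are
#' possible.
#'
#' @param ratings A validated rating table covering exactly `n_assessors`
#'   assessors per (image, landmark).
#' @param k Majority threshold (assessors), default 2.
#' @param n_assessors Required assessor coverage per (image, landmark),
#'   default 3.
#' @return A tibble with one row per (image, landmark): logical
#'   `landmark_inadequate`, list-columns `reasons_majority` and
#'   `excluded_annotations`.
#' @export
resolve_adequacy <- function(ratings, k = 2, n_assessors = 3) {
  r <- validate_ratings(ratings)
  cov <- dplyr::summarise(
    dplyr::group_by(r, .data$image_id, .data$landmark),
    n_assessors_seen = dplyr::n_distinct(.data$assessor_id),
    .groups = "drop")
  bad <- cov$n_assessors_seen != n_assessors
  if (any(bad)) {
    b <- cov[which(bad)[1], ]
    stop(sprintf("image %s, landmark %s has %d assessor rating(s), expected %d",
                 b$image_id, b$landmark, b$n_assessors_seen, n_assessors),
         call. = FALSE)
  }
  flags <- r[!is.na(r$annotator_id), ]
  keys <- dplyr::distinct(r, .data$image_id, .data$landmark)

  lw <- dplyr::summarise(
    dplyr::group_by(flags, .data$image_id, .data$landmark),
    landmark_inadequate = dplyr::n_distinct(.data$assessor_id) >= k,
    .groups = "drop")
  rw <- dplyr::summarise(
    dplyr::group_by(flags, .data$image_id, .data$landmark, .data$reason),
    n_cite = dplyr::n_distinct(.data$assessor_id), .groups = "drop")
  rw <- dplyr::summarise(
    dplyr::group_by(rw[rw$n_cite >= k, ], .data$image_id, .data$landmark),
    reasons_majority = list(sort(unique(.data$reason))), .groups = "drop")
  aw <- dplyr::summarise(
    dplyr::group_by(flags, .data$image_id, .data$landmark, .data$annotator_id),
    n_flag = dplyr::n_distinct(.data$assessor_id), .groups = "drop")
  aw <- dplyr::summarise(
    dplyr::group_by(aw[aw$n_flag >= k, ], .data$image_id, .data$landmark),
    excluded_annotations = list(sort(unique(.data$annotator_id))),
    .groups = "drop")

  out <- dplyr::left_join(keys, lw, by = c("image_id", "landmark"))
  out <- dplyr::left_join(out, rw, by = c("image_id", "landmark"))
  out <- dplyr::left_join(out, aw, by = c("image_id", "landmark"))
  out$landmark_inadequate[is.na(out$landmark_inadequate)] <- FALSE
  out$reasons_majority <- purrr::map(out$reasons_majority,
                                     function(x) if (is.null(x)) character() else x)
  out$excluded_annotations <- purrr::map(out$excluded_annotations,
                                         function(x) if (is.null(x)) character() else x)
  dplyr::arrange(out, .data$image_id, .data$landmark)
}

#' Landmark-wise inadequacy table
#'
#' Counts, per review landmark, the images whose landmark was inadequate by
#' majority, plus an `any_landmark` row counting images with at least one
#' inadequate landmark. Percentages are of `n_images`, rounded to two
#' decimals.
#'
#' @param resolutions Output of [resolve_adequacy()].
#' @param n_images Total number of images in the study.
#' @return A tibble with columns `landmark`, `cases`, `percentage`.
#' @export
tabulate_landmark_wise <- function(resolutions, n_images) {
  if (n_images <= 0) stop("n_images must be positive", call. = FALSE)
  inad <- resolutions[resolutions$landmark_inadequate, ]
  per <- dplyr::count(inad, .data$landmark, name = "cases")
  per <- dplyr::left_join(
    tibble::tibble(landmark = pt_review_landmarks()), per, by = "landmark")
  per$cases[is.na(per$cases)] <- 0L
  any_row <- tibble::tibble(landmark = "any_landmark",
                            cases = dplyr::n_distinct(inad$image_id))
  out <- dplyr::bind_rows(per, any_row)
  out$percentage <- round(100 * out$cases / n_images, 2)
  out
}

#' Reason-wise inadequacy table
#'
#' Counts, per (review landmark, reason), the images for which that reason
#' reached the assessor majority, with percentages of `n_images` rounded to
#' two decimals. All landmark-reason combinations appear, zeros included.
#'
#' @inheritParams tabulate_landmark_wise
#' @return A tibble with columns `landmark`, `reason`, `cases`, `percentage`.
#' @export
tabulate_reason_wise <- function(resolutions, n_images) {
  if (n_images <= 0) stop("n_images must be positive", call. = FALSE)
  long <- tidyr::unnest(
    resolutions[, c("image_id", "landmark", "reasons_majority")],
    "reasons_majority")
  grid <- tidyr::expand_grid(landmark = pt_review_landmarks(),
                             reason = pt_flag_reasons())
  if (nrow(long) > 0) {
    counts <- dplyr::count(long, .data$landmark,
                           reason = .data$reasons_majority, name = "cases")
    grid <- dplyr::left_join(grid, counts, by = c("landmark", "reason"))
  } else {
    grid$cases <- NA_integer_
  }
  grid$cases[is.na(grid$cases)] <- 0L
  grid$percentage <- round(100 * grid$cases / n_images, 2)
  grid
}

review_landmark_parameter <- function() {
  tibble::tibble(
    landmark = pt_review_landmarks(),
    definition = c("PT_a", "PT_a", "PT_m", "PT_m", "PT_m", "PT_m"),
    method = c("estimation", "estimation", "calculation", "estimation",
               "calculation", "estimation"))
}

#' Annotation exclusion mask
#'
#' Expands the majority-excluded annotations into the measurement rows they
#' invalidate. Each review landmark maps to exactly one parameter variant
#' (ASIS centre and pubic tubercle to the anatomical definition; the
#' calculated / estimated femoral-head centre and sacral midpoint to the
#' mechanical definition's calculation / estimation variant), so excluding an
#' annotator's landmark removes that annotator's measurement of that variant
#' only.
#'
#' @inheritParams tabulate_landmark_wise
#' @return A tibble with columns `image_id`, `landmark`, `annotator_id`,
#'   `definition`, `method`; one row per excluded (image, landmark,
#'   annotator).
#' @export
exclusion_mask <- function(resolutions) {
  long <- tidyr::unnest(
    resolutions[, c("image_id", "landmark", "excluded_annotations")],
    "excluded_annotations")
  if (nrow(long) == 0) {
    return(tibble::tibble(image_id = character(), landmark = character(),
                          annotator_id = character(), definition = character(),
                          method = character()))
  }
  names(long)[names(long) == "excluded_annotations"] <- "annotator_id"
  dplyr::left_join(long, review_landmark_parameter(), by = "landmark")
}
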