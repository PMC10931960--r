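#' Circumcentre of three points
#'
#' Returns the centre of the unique circle through three non-collinear
#' points. Used to recover a femoral-head centre from three points annotated
#' on the head's contour: three points determine the circle exactly, so no
#' least-squares fit is needed and the result is deterministic.
#'
#' Collinearity is judged scale-free: the triangle is degenerate when its
#' area is below `tol` times the squared longest side.
#'
#' @param p1,p2,p3 Numeric `c(x, y)` pairs, pixel coordinates.
#' @param tol Relative area tolerance for collinearity.
#' @param landmark Optional landmark name used in the degenerate-geometry
#'   error message.
#' @return Numeric `c(x, y)` of the circumcentre.
#' @export
circumcentre <- function(p1, p2, p3, tol = 1e-6, landmark = "contour") {
  stopifnot(length(p1) == 2, length(p2) == 2, length(p3) == 2)
  a <- p2 - p1
  b <- p3 - p1
  cross <- a[1] * b[2] - a[2] * b[1]
  area <- abs(cross) / 2
  longest2 <- max(sum(a^2), sum(b^2), sum((p3 - p2)^2))
  if (area < tol * longest2) {
    stop(sprintf("degenerate geometry for '%s': contour points are collinear",
                 landmark), call. = FALSE)
  }
  a2 <- sum(a^2)
  b2 <- sum(b^2)
  ux <- (b[2] * a2 - a[2] * b2) / (2 * cross)
  uy <- (a[1] * b2 - b[1] * a2) / (2 * cross)
  unname(p1 + c(ux, uy))
}

get_points <- function(landmarks, image_id, annotator_id, landmark) {
  rows <- landmarks[landmarks$image_id == image_id &
                    landmarks$annotator_id == annotator_id &
                    landmarks$landmark == landmark, , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  rows <- rows[order(rows$point_index), , drop = FALSE]
  cbind(rows$x, rows$y)
}

point_or_stop <- function(landmarks, image_id, annotator_id, landmark) {
  p <- get_points(landmarks, image_id, annotator_id, landmark)
  if (is.null(p)) {
    stop(sprintf("missing landmark '%s' (image %s, annotator %s)",
                 landmark, image_id, annotator_id), call. = FALSE)
  }
  p
}

#' Derived measurement points
#'
#' `femoral_head_centre_cal()` computes the bicoxofemoral centre under the
#' calculation method: the circumcentre of each femoral head's three contour
#' points, then the midpoint of the two per-head centres (the two heads are
#' weighted equally, matching the bicoxofemoral-axis convention).
#' `sacral_midpoint_cal()` is the arithmetic midpoint of the annotated
#' anterior and posterior ends of the sacral endplate.
#'
#' @param landmarks A validated landmark table.
#' @param image_id,annotator_id Identifiers selecting one annotation set.
#' @return Numeric `c(x, y)` in pixels.
#' @export
femoral_head_centre_cal <- function(landmarks, image_id, annotator_id) {
  c1 <- point_or_stop(landmarks, image_id, annotator_id, "femoral_head_1_contour")
  c2 <- point_or_stop(landmarks, image_id, annotator_id, "femoral_head_2_contour")
  o1 <- circumcentre(c1[1, ], c1[2, ], c1[3, ], landmark = "femoral_head_1_contour")
  o2 <- circumcentre(c2[1, ], c2[2, ], c2[3, ], landmark = "femoral_head_2_contour")
  (o1 + o2) / 2
}

#' @rdname femoral_head_centre_cal
#' @export
sacral_midpoint_cal <- function(landmarks, image_id, annotator_id) {
  a <- point_or_stop(landmarks, image_id, annotator_id, "sacral_plate_anterior")
  p <- point_or_stop(landmarks, image_id, annotator_id, "sacral_plate_posterior")
  (a[1, ] + p[1, ]) / 2
}

#' Signed angle of a line to the vertical gravity line
#'
#' The gravity line is the image vertical (standing acquisition implies plumb
#' vertical). The angle is measured between the inferior-to-superior
#' direction of the landmark line and the upward vertical, in degrees, and is
#' signed: positive when the superior point lies toward the posterior side of
#' the image, so posterior pelvic tilt is positive. Because patients may face
#' either image direction, `posterior_direction` states which x direction is
#' posterior for the dataset.
#'
#' @param inferior,superior Numeric `c(x, y)` pairs; image y increases
#'   downward, so the superior point must have strictly smaller y.
#' @param posterior_direction `"neg_x"` or `"pos_x"`.
#' @return Signed angle in degrees, in (-90, 90).
#' @export
angle_to_vertical <- function(inferior, superior,
                              posterior_direction = c("neg_x", "pos_x")) {
  posterior_direction <- match.arg(posterior_direction)
  if (all(inferior == superior)) {
    stop("cannot measure an angle between coincident points", call. = FALSE)
  }
  dy_up <- inferior[2] - superior[2]
  if (dy_up <= 0) {
    stop("orientation error: superior point must lie strictly above the inferior point",
         call. = FALSE)
  }
  dx <- superior[1] - inferior[1]
  s <- if (posterior_direction == "pos_x") 1 else -1
  unname(atan2(s * dx, dy_up) * 180 / pi)
}

parameter_label <- function(definition, method) {
  dplyr::case_when(
    definition == "PT_a" ~ "PT_a",
    method == "calculation" ~ "PT_m_cal",
    TRUE ~ "PT_m_est")
}

#' Compute a pelvic tilt measurement
#'
#' Computes one signed pelvic-tilt angle for an (image, annotator) pair.
#' Under the mechanical definition (`PT_m`) the line runs from the centre of
#' the femoral heads (inferior) to the midpoint of the sacral plate
#' (superior); `method` chooses between the calculation variant (centres
#' derived from contour/endplate annotations) and the estimation variant
#' (directly clicked points). Under the anatomical definition (`PT_a`) the
#' line runs from the pubic tubercle (inferior) to the ASIS centre
#' (superior); both are single clicked points, so `PT_a` exists only with
#' `method = "estimation"`.
#'
#' @inheritParams femoral_head_centre_cal
#' @param definition `"PT_m"` or `"PT_a"`.
#' @param method `"calculation"` or `"estimation"`.
#' @inheritParams angle_to_vertical
#' @return A one-row tibble with columns `image_id`, `annotator_id`,
#'   `definition`, `method`, `angle_deg`.
#' @export
compute_pt <- function(landmarks, image_id, annotator_id,
                       definition = c("PT_m", "PT_a"),
                       method = c("calculation", "estimation"),
                       posterior_direction = c("neg_x", "pos_x")) {
  definition <- match.arg(definition)
  method <- match.arg(method)
  posterior_direction <- match.arg(posterior_direction)
  if (definition == "PT_a") {
    if (method != "estimation") {
      stop("PT_a exists only under the estimation method", call. = FALSE)
    }
    inferior <- point_or_stop(landmarks, image_id, annotator_id,
                              "pubic_tubercle")[1, ]
    superior <- point_or_stop(landmarks, image_id, annotator_id,
                              "asis_centre")[1, ]
  } else if (method == "calculation") {
    inferior <- femoral_head_centre_cal(landmarks, image_id, annotator_id)
    superior <- sacral_midpoint_cal(landmarks, image_id, annotator_id)
  } else {
    inferior <- point_or_stop(landmarks, image_id, annotator_id,
                              "femoral_head_centre_est")[1, ]
    superior <- point_or_stop(landmarks, image_id, annotator_id,
                              "sacral_midpoint_est")[1, ]
  }
  tibble::tibble(
    image_id = as.character(image_id),
    annotator_id = as.character(annotator_id),
    definition = definition,
    method = method,
    angle_deg = angle_to_vertical(inferior, superior, posterior_direction))
}

#' Compute every available pelvic-tilt measurement
#'
#' Computes, for each (image, annotator) pair, every parameter variant whose
#' required landmarks are present: `PT_m` calculation, `PT_m` estimation and
#' `PT_a`. Pairs whose landmarks fail geometrically (collinear contour
#' points, inverted line orientation) produce a warning and are skipped;
#' valid measurements are still returned.
#'
#' @inheritParams compute_pt
#' @return A tibble with columns `image_id`, `annotator_id`, `definition`,
#'   `method`, `angle_deg`, one row per computable measurement.
#' @export
compute_pt_all <- function(landmarks, posterior_direction = c("neg_x", "pos_x")) {
  posterior_direction <- match.arg(posterior_direction)
  empty <- tibble::tibble(image_id = character(), annotator_id = character(),
                          definition = character(), method = character(),
                          angle_deg = double())
  if (nrow(landmarks) == 0) return(empty)
  lm <- dplyr::arrange(landmarks, .data$image_id, .data$annotator_id,
                       .data$landmark, .data$point_index)
  groups <- split(seq_len(nrow(lm)),
                  paste(lm$image_id, lm$annotator_id, sep = "\r"))
  variants <- list(c("PT_m", "calculation"), c("PT_m", "estimation"),
                   c("PT_a", "estimation"))
  needed <- list(
    c("femoral_head_1_contour", "femoral_head_2_contour",
      "sacral_plate_anterior", "sacral_plate_posterior"),
    c("femoral_head_centre_est", "sacral_midpoint_est"),
    c("pubic_tubercle", "asis_centre"))

  rows <- lapply(groups, function(i) {
    lms <- lm$landmark[i]
    xs <- lm$x[i]
    ys <- lm$y[i]
    img <- lm$image_id[i[1]]
    ann <- lm$annotator_id[i[1]]
    pick <- function(name) {
      j <- which(lms == name)  # rows already ordered by point_index
      cbind(xs[j], ys[j])
    }
    angles <- rep(NA_real_, 3)
    for (v in 1:3) {
      if (!all(needed[[v]] %in% lms)) next
      a <- tryCatch({
        if (v == 1) {
          c1 <- pick("femoral_head_1_contour")
          c2 <- pick("femoral_head_2_contour")
          o1 <- circumcentre(c1[1, ], c1[2, ], c1[3, ],
                             landmark = "femoral_head_1_contour")
          o2 <- circumcentre(c2[1, ], c2[2, ], c2[3, ],
                             landmark = "femoral_head_2_contour")
          inferior <- (o1 + o2) / 2
          superior <- (pick("sacral_plate_anterior")[1, ] +
                       pick("sacral_plate_posterior")[1, ]) / 2
        } else if (v == 2) {
          inferior <- pick("femoral_head_centre_est")[1, ]
          superior <- pick("sacral_midpoint_est")[1, ]
        } else {
          inferior <- pick("pubic_tubercle")[1, ]
          superior <- pick("asis_centre")[1, ]
        }
        angle_to_vertical(inferior, superior, posterior_direction)
      }, error = function(e) {
        warning(sprintf("skipping %s/%s for image %s, annotator %s: %s",
                        variants[[v]][1], variants[[v]][2], img, ann,
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
      angles[v] <- a
    }
    ok <- !is.na(angles)
    if (!any(ok)) return(NULL)
    list(image_id = rep(img, sum(ok)), annotator_id = rep(ann, sum(ok)),
         definition = vapply(variants[ok], `[`, "", 1),
         method = vapply(variants[ok], `[`, "", 2),
         angle_deg = angles[ok])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- tibble::tibble(
    image_id = unname(unlist(lapply(rows, `[[`, "image_id"))),
    annotator_id = unname(unlist(lapply(rows, `[[`, "annotator_id"))),
    definition = unname(unlist(lapply(rows, `[[`, "definition"))),
    method = unname(unlist(lapply(rows, `[[`, "method"))),
    angle_deg = unname(unlist(lapply(rows, `[[`, "angle_deg"))))
  dplyr::arrange(out, .data$image_id, .data$annotator_id, .data$definition,
                 .data$method)
}
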