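#' Synthetic pelvis template
#'
#' Defines the stick-figure pelvis geometry from which noiseless landmark
#' annotations are constructed. The pipeline consumes coordinates only, so no
#' image is rendered: the template fixes the femoral-head centre, the
#' separation and radius of the two head circles, the distance and direction
#' to the sacral-plate midpoint (set by the true mechanical pelvic tilt), the
#' endplate half-width and slope, and the positions of the ASIS centre and
#' pubic tubercle along the anterior-pelvic-plane line (set by the true
#' anatomical pelvic tilt). Magnitudes default to a plausible standing
#' sagittal pelvis at EOS-like pixel scale; they are configuration, not
#' science. Computing pelvic tilt on the noiseless realization recovers the
#' template's true angles exactly.
#'
#' @param true_pt_m,true_pt_a True mechanical / anatomical pelvic tilt,
#'   degrees, posterior tilt positive.
#' @param femoral_centre Bicoxofemoral centre, pixels `c(x, y)`.
#' @param head_separation Distance between the two femoral-head centres,
#'   pixels (heads nearly superimpose on a sagittal view).
#' @param head_radius Femoral-head radius, pixels.
#' @param sacral_distance Femoral centre to sacral-plate midpoint, pixels.
#' @param endplate_halfwidth Half-width of the sacral endplate, pixels.
#' @param sacral_slope_deg Endplate inclination from the horizontal, degrees.
#' @param asis_distance,pubic_distance Distances from the reference origin
#'   (the femoral centre) to the ASIS centre (above) and the pubic tubercle
#'   (below) along the anterior-pelvic-plane line, pixels.
#' @param posterior_direction Which image x direction is posterior
#'   (`"neg_x"` or `"pos_x"`).
#' @return A `pelvis_template` list.
#' @export
pelvis_template <- function(true_pt_m = 12, true_pt_a = 8,
                            femoral_centre = c(250, 300),
                            head_separation = 40, head_radius = 25,
                            sacral_distance = 150, endplate_halfwidth = 25,
                            sacral_slope_deg = 40,
                            asis_distance = 120, pubic_distance = 80,
                            posterior_direction = c("neg_x", "pos_x")) {
  posterior_direction <- match.arg(posterior_direction)
  stopifnot(abs(true_pt_m) < 90, abs(true_pt_a) < 90,
            head_radius > 0, sacral_distance > 0, endplate_halfwidth > 0,
            asis_distance > 0, pubic_distance > 0)
  structure(
    list(true_pt_m = true_pt_m, true_pt_a = true_pt_a,
         femoral_centre = femoral_centre, head_separation = head_separation,
         head_radius = head_radius, sacral_distance = sacral_distance,
         endplate_halfwidth = endplate_halfwidth,
         sacral_slope_deg = sacral_slope_deg,
         asis_distance = asis_distance, pubic_distance = pubic_distance,
         posterior_direction = posterior_direction),
    class = "pelvis_template")
}

expand_landmark_param <- function(x, what) {
  landmarks <- pt_landmarks()$landmark
  if (is.null(names(x))) {
    if (length(x) != 1) stop(what, " must be a scalar or a named vector",
                             call. = FALSE)
    return(stats::setNames(rep(x, length(landmarks)), landmarks))
  }
  unknown <- setdiff(names(x), landmarks)
  if (length(unknown) > 0) {
    stop(what, " names unknown landmark(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(rep(0, length(landmarks)), landmarks)
  out[names(x)] <- x
  out
}

#' Annotator noise model
#'
#' Generative counterparts of the review's reason taxonomy. Per-point
#' Gaussian jitter emulates ordinary click imprecision; per-landmark outlier
#' contamination displaces a whole landmark far from its target (for the
#' ASIS centre the displacement is lateral, emulating annotators who
#' overlook the contralateral iliac spine and mark one side); bad-quality
#' images inflate every landmark's jitter by a common multiplier; anomaly
#' images displace the true sacral endplate so that every annotator marks
#' the offset plate.
#'
#' @param sigma_px Gaussian jitter SD in pixels; scalar or per-landmark
#'   named vector (unnamed scalar applies to all landmarks; named entries
#'   not listed default to 0).
#' @param outlier_prob Per-annotation probability of an outlier displacement;
#'   scalar or per-landmark named vector. Defaults reflect that directly
#'   estimated landmarks (ASIS centre, estimated femoral-head centre) attract
#'   far more outliers than contour-derived ones.
#' @param outlier_shift_px Range `c(lo, hi)` of outlier displacement
#'   magnitudes, pixels.
#' @param bad_quality_image_prob Probability an image is low quality.
#' @param bad_quality_sigma_multiplier Jitter multiplier on low-quality
#'   images.
#' @param anomaly_image_prob Probability an image carries a sacral anomaly
#'   (e.g. a lumbosacral transitional vertebra mimicking the endplate).
#' @param anomaly_endplate_offset_px Upward displacement of the apparent
#'   endplate on anomaly images, pixels.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma_px = 2,
                        outlier_prob = c(asis_centre = 0.08,
                                         pubic_tubercle = 0.02,
                                         femoral_head_1_contour = 0.02,
                                         femoral_head_2_contour = 0.02,
                                         femoral_head_centre_est = 0.07,
                                         sacral_plate_anterior = 0.015,
                                         sacral_plate_posterior = 0.015,
                                         sacral_midpoint_est = 0.02),
                        outlier_shift_px = c(30, 60),
                        bad_quality_image_prob = 0.12,
                        bad_quality_sigma_multiplier = 3,
                        anomaly_image_prob = 0.07,
                        anomaly_endplate_offset_px = 20) {
  sigma_px <- expand_landmark_param(sigma_px, "sigma_px")
  outlier_prob <- expand_landmark_param(outlier_prob, "outlier_prob")
  stopifnot(all(sigma_px >= 0), all(outlier_prob >= 0 & outlier_prob <= 1),
            length(outlier_shift_px) == 2,
            outlier_shift_px[1] <= outlier_shift_px[2],
            bad_quality_image_prob >= 0, bad_quality_image_prob <= 1,
            bad_quality_sigma_multiplier >= 0,
            anomaly_image_prob >= 0, anomaly_image_prob <= 1)
  structure(
    list(sigma_px = sigma_px, outlier_prob = outlier_prob,
         outlier_shift_px = outlier_shift_px,
         bad_quality_image_prob = bad_quality_image_prob,
         bad_quality_sigma_multiplier = bad_quality_sigma_multiplier,
         anomaly_image_prob = anomaly_image_prob,
         anomaly_endplate_offset_px = anomaly_endplate_offset_px),
    class = "noise_model")
}

#' Assessor behaviour model
#'
#' An assessor flags an annotation when its review-level position lies
#' further than `flag_threshold_px` from the true position, and
#' independently flips any verdict with probability `assessor_error_prob`
#' (a flipped-on flag carries reason `other`).
#'
#' @param flag_threshold_px Distance from truth beyond which an assessor
#'   flags, pixels.
#' @param assessor_error_prob Independent verdict-flip probability.
#' @return An `assessor_model` list.
#' @export
assessor_model <- function(flag_threshold_px = 15, assessor_error_prob = 0.05) {
  stopifnot(flag_threshold_px > 0,
            assessor_error_prob >= 0, assessor_error_prob <= 1)
  structure(list(flag_threshold_px = flag_threshold_px,
                 assessor_error_prob = assessor_error_prob),
            class = "assessor_model")
}

pt_direction <- function(angle_deg, posterior_direction) {
  s <- if (posterior_direction == "pos_x") 1 else -1
  th <- angle_deg * pi / 180
  c(s * sin(th), -cos(th))
}

truth_landmarks_one <- function(template, image_id, pt_m, pt_a) {
  fc <- template$femoral_centre
  s <- if (template$posterior_direction == "pos_x") 1 else -1
  u_m <- pt_direction(pt_m, template$posterior_direction)
  u_a <- pt_direction(pt_a, template$posterior_direction)

  sacral_mid <- fc + template$sacral_distance * u_m
  slope <- template$sacral_slope_deg * pi / 180
  anterior_dir <- c(-s * cos(slope), sin(slope))
  sacral_ant <- sacral_mid + template$endplate_halfwidth * anterior_dir
  sacral_post <- sacral_mid - template$endplate_halfwidth * anterior_dir

  head1 <- fc + c(-template$head_separation / 2, 0)
  head2 <- fc + c(template$head_separation / 2, 0)
  phi <- c(90, 210, 330) * pi / 180
  contour <- function(centre) {
    cbind(centre[1] + template$head_radius * cos(phi),
          centre[2] + template$head_radius * sin(phi))
  }
  c1 <- contour(head1)
  c2 <- contour(head2)

  asis <- fc + template$asis_distance * u_a
  pubic <- fc - template$pubic_distance * u_a

  tibble::tibble(
    image_id = image_id,
    annotator_id = "truth",
    landmark = c("asis_centre", "pubic_tubercle",
                 rep("femoral_head_1_contour", 3),
                 rep("femoral_head_2_contour", 3),
                 "femoral_head_centre_est",
                 "sacral_plate_anterior", "sacral_plate_posterior",
                 "sacral_midpoint_est"),
    point_index = c(0L, 0L, 0:2, 0:2, 0L, 0L, 0L, 0L),
    x = c(asis[1], pubic[1], c1[, 1], c2[, 1], fc[1],
          sacral_ant[1], sacral_post[1], sacral_mid[1]),
    y = c(asis[2], pubic[2], c1[, 2], c2[, 2], fc[2],
          sacral_ant[2], sacral_post[2], sacral_mid[2]))
}

#' Generate noiseless ground-truth annotations
#'
#' Draws a true pelvic tilt per image (template value plus uniform jitter,
#' independently for the mechanical and anatomical definitions) and
#' constructs landmark coordinates that invert the measurement geometry:
#' running [compute_pt_all()] on the output recovers the drawn truths
#' exactly. Contour triples sit at three fixed angles on each head circle.
#'
#' @param template A [pelvis_template()].
#' @param n_images Number of images.
#' @param pt_jitter_deg Half-width of the uniform per-image tilt jitter,
#'   degrees.
#' @param seed Integer seed.
#' @return A list with `landmarks` (validated tibble, annotator `"truth"`)
#'   and `truth` (tibble `image_id`, `true_pt_m_deg`, `true_pt_a_deg`).
#' @export
generate_truth <- function(template, n_images, pt_jitter_deg = 0, seed = 1) {
  stopifnot(inherits(template, "pelvis_template"), n_images >= 0)
  set.seed(seed)
  ids <- sprintf("img%04d", seq_len(n_images))
  pt_m <- template$true_pt_m +
    stats::runif(n_images, -pt_jitter_deg, pt_jitter_deg)
  pt_a <- template$true_pt_a +
    stats::runif(n_images, -pt_jitter_deg, pt_jitter_deg)
  lm <- purrr::map(seq_len(n_images), function(i) {
    truth_landmarks_one(template, ids[i], pt_m[i], pt_a[i])
  })
  lm <- dplyr::bind_rows(lm)
  if (nrow(lm) == 0) {
    lm <- empty_landmarks()
  } else {
    vocab <- pt_landmarks()
    lm$method <- stats::setNames(vocab$method, vocab$landmark)[lm$landmark]
    lm <- validate_landmarks(lm)
  }
  list(landmarks = lm,
       truth = tibble::tibble(image_id = ids, true_pt_m_deg = pt_m,
                              true_pt_a_deg = pt_a))
}

#' Corrupt ground-truth annotations into a multi-annotator study
#'
#' Replicates the noiseless landmarks across annotators and injects the
#' noise model's mechanisms in a fixed order: image-level anomaly
#' displacement of the sacral endplate (shared by all annotators, who mark
#' the offset plate), per-annotation outlier shifts (all points of the
#' landmark move together; the ASIS outlier is a lateral shift), and
#' per-point Gaussian jitter whose SD is inflated on bad-quality images.
#' Every injected corruption is recorded in a ledger for downstream assessor
#' simulation and replay.
#'
#' @param truth Output of [generate_truth()] (or its `landmarks` tibble).
#' @param n_annotators Number of simulated annotators.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A list with `landmarks` (corrupted annotations for
#'   `ann1..annN`), `ledger` (tibble `image_id`, `annotator_id`, `landmark`,
#'   `type`, `shift_x`, `shift_y`, `magnitude`) and `image_flags` (tibble
#'   `image_id`, `bad_quality`, `anomaly`).
#' @export
corrupt <- function(truth, n_annotators = 5, noise = noise_model(), seed = 1) {
  stopifnot(inherits(noise, "noise_model"))
  lm <- if (is.list(truth) && !is.data.frame(truth)) truth$landmarks else truth
  set.seed(seed)
  images <- sort(unique(lm$image_id))
  n_images <- length(images)
  bad_q <- stats::runif(n_images) < noise$bad_quality_image_prob
  anomaly <- stats::runif(n_images) < noise$anomaly_image_prob
  image_flags <- tibble::tibble(image_id = images, bad_quality = bad_q,
                                anomaly = anomaly)

  sacral_set <- c("sacral_plate_anterior", "sacral_plate_posterior",
                  "sacral_midpoint_est")
  base <- lm
  anom_rows <- base$image_id %in% images[anomaly] &
    base$landmark %in% sacral_set
  base$y[anom_rows] <- base$y[anom_rows] - noise$anomaly_endplate_offset_px

  ledger <- list()
  if (any(bad_q)) {
    ledger$bad <- tibble::tibble(
      image_id = images[bad_q], annotator_id = NA_character_,
      landmark = NA_character_, type = "bad_quality",
      shift_x = NA_real_, shift_y = NA_real_,
      magnitude = noise$bad_quality_sigma_multiplier)
  }
  if (any(anomaly)) {
    ledger$anom <- tibble::tibble(
      image_id = images[anomaly], annotator_id = NA_character_,
      landmark = NA_character_, type = "anomaly",
      shift_x = 0, shift_y = -noise$anomaly_endplate_offset_px,
      magnitude = noise$anomaly_endplate_offset_px)
  }

  out <- vector("list", n_annotators)
  for (a in seq_len(n_annotators)) {
    ann_id <- sprintf("ann%d", a)
    df <- base
    df$annotator_id <- ann_id

    keys <- dplyr::distinct(df, .data$image_id, .data$landmark)
    keys <- dplyr::arrange(keys, .data$image_id, .data$landmark)
    hit <- stats::runif(nrow(keys)) < noise$outlier_prob[keys$landmark]
    if (any(hit)) {
      flagged <- keys[hit, ]
      shifts <- purrr::map(seq_len(nrow(flagged)), function(i) {
        mag <- stats::runif(1, noise$outlier_shift_px[1],
                            noise$outlier_shift_px[2])
        if (flagged$landmark[i] == "asis_centre") {
          dir <- c(sample(c(-1, 1), 1), 0)
        } else {
          th <- stats::runif(1, 0, 2 * pi)
          dir <- c(cos(th), sin(th))
        }
        c(mag * dir, mag)
      })
      shifts <- do.call(rbind, shifts)
      flagged$shift_x <- shifts[, 1]
      flagged$shift_y <- shifts[, 2]
      flagged$magnitude <- shifts[, 3]
      df <- dplyr::left_join(df, flagged, by = c("image_id", "landmark"))
      moved <- !is.na(df$shift_x)
      df$x[moved] <- df$x[moved] + df$shift_x[moved]
      df$y[moved] <- df$y[moved] + df$shift_y[moved]
      df <- df[, landmark_cols]
      flagged$annotator_id <- ann_id
      flagged$type <- "outlier"
      ledger[[paste0("out", a)]] <-
        flagged[, c("image_id", "annotator_id", "landmark", "type",
                    "shift_x", "shift_y", "magnitude")]
    }

    sigma <- noise$sigma_px[df$landmark] *
      ifelse(df$image_id %in% images[bad_q],
             noise$bad_quality_sigma_multiplier, 1)
    df$x <- df$x + stats::rnorm(nrow(df), 0, sigma)
    df$y <- df$y + stats::rnorm(nrow(df), 0, sigma)
    out[[a]] <- df
  }
  landmarks <- dplyr::bind_rows(out)
  landmarks <- if (nrow(landmarks) > 0) validate_landmarks(landmarks) else
    empty_landmarks()
  ledger <- if (length(ledger) > 0) dplyr::bind_rows(ledger) else
    tibble::tibble(image_id = character(), annotator_id = character(),
                   landmark = character(), type = character(),
                   shift_x = double(), shift_y = double(),
                   magnitude = double())
  list(landmarks = landmarks,
       ledger = dplyr::arrange(ledger, .data$type, .data$image_id),
       image_flags = image_flags)
}

raw_to_review_landmark <- c(
  asis_centre = "asis_centre",
  pubic_tubercle = "pubic_tubercle",
  femoral_head_1_contour = "femoral_head_centre_cal",
  femoral_head_2_contour = "femoral_head_centre_cal",
  femoral_head_centre_est = "femoral_head_centre_est",
  sacral_plate_anterior = "sacral_midpoint_cal",
  sacral_plate_posterior = "sacral_midpoint_cal",
  sacral_midpoint_est = "sacral_midpoint_est")

#' Review-level landmark positions
#'
#' Reduces raw annotations to the six positions assessors review: the four
#' directly clicked points plus the contour-derived femoral-head centre and
#' sacral-endplate midpoint. Degenerate contours yield `NA` coordinates.
#'
#' @param landmarks A validated landmark table.
#' @return A tibble `image_id`, `annotator_id`, `landmark` (review-level),
#'   `x`, `y`.
#' @export
review_positions <- function(landmarks) {
  if (nrow(landmarks) == 0) {
    return(tibble::tibble(image_id = character(), annotator_id = character(),
                          landmark = character(), x = double(), y = double()))
  }
  lm <- dplyr::arrange(landmarks, .data$image_id, .data$annotator_id,
                       .data$landmark, .data$point_index)
  groups <- split(seq_len(nrow(lm)),
                  paste(lm$image_id, lm$annotator_id, sep = "\r"))
  direct_set <- c("asis_centre", "pubic_tubercle", "femoral_head_centre_est",
                  "sacral_midpoint_est")
  rows <- lapply(groups, function(i) {
    lms <- lm$landmark[i]
    xs <- lm$x[i]
    ys <- lm$y[i]
    pick <- function(name) {
      j <- which(lms == name)
      cbind(xs[j], ys[j])
    }
    d <- which(lms %in% direct_set)
    name <- lms[d]
    x <- xs[d]
    y <- ys[d]
    if (all(c("femoral_head_1_contour", "femoral_head_2_contour") %in% lms)) {
      fh <- tryCatch({
        c1 <- pick("femoral_head_1_contour")
        c2 <- pick("femoral_head_2_contour")
        (circumcentre(c1[1, ], c1[2, ], c1[3, ]) +
         circumcentre(c2[1, ], c2[2, ], c2[3, ])) / 2
      }, error = function(e) c(NA_real_, NA_real_))
      name <- c(name, "femoral_head_centre_cal")
      x <- c(x, fh[1])
      y <- c(y, fh[2])
    }
    if (all(c("sacral_plate_anterior", "sacral_plate_posterior") %in% lms)) {
      sm <- (pick("sacral_plate_anterior")[1, ] +
             pick("sacral_plate_posterior")[1, ]) / 2
      name <- c(name, "sacral_midpoint_cal")
      x <- c(x, sm[1])
      y <- c(y, sm[2])
    }
    list(image_id = rep(lm$image_id[i[1]], length(name)),
         annotator_id = rep(lm$annotator_id[i[1]], length(name)),
         landmark = name, x = x, y = y)
  })
  tibble::tibble(
    image_id = unname(unlist(lapply(rows, `[[`, "image_id"))),
    annotator_id = unname(unlist(lapply(rows, `[[`, "annotator_id"))),
    landmark = unname(unlist(lapply(rows, `[[`, "landmark"))),
    x = unname(unlist(lapply(rows, `[[`, "x"))),
    y = unname(unlist(lapply(rows, `[[`, "y"))))
}

#' Simulate the three-assessor adequacy review
#'
#' Each assessor deterministically flags any annotation whose review-level
#' position lies further than the model threshold from the true position,
#' then independently flips verdicts at the model error probability. Reasons
#' are taken from the corruption ledger: an injected outlier shift yields
#' `outlier`, a sacral landmark on an anomaly image yields `anomaly`, any
#' landmark on a bad-quality image yields `bad_quality`, and anything else
#' (including flipped-on flags) yields `other`.
#'
#' @param corrupted Output of [corrupt()].
#' @param truth Output of [generate_truth()] (or its `landmarks` tibble).
#' @param model An [assessor_model()].
#' @param n_assessors Number of assessors.
#' @param seed Integer seed.
#' @return A validated rating table (see [read_ratings()]).
#' @export
simulate_assessors <- function(corrupted, truth, model = assessor_model(),
                               n_assessors = 3, seed = 1) {
  stopifnot(inherits(model, "assessor_model"))
  truth_lm <- if (is.list(truth) && !is.data.frame(truth)) truth$landmarks else
    truth
  set.seed(seed)
  pos <- review_positions(corrupted$landmarks)
  tru <- review_positions(truth_lm)[, c("image_id", "landmark", "x", "y")]
  names(tru)[3:4] <- c("x_true", "y_true")
  pos <- dplyr::left_join(pos, tru, by = c("image_id", "landmark"))
  d <- sqrt((pos$x - pos$x_true)^2 + (pos$y - pos$y_true)^2)
  d[is.na(d)] <- Inf
  pos$base_flag <- d > model$flag_threshold_px

  out_led <- corrupted$ledger[corrupted$ledger$type == "outlier", ]
  out_led$review_landmark <- raw_to_review_landmark[out_led$landmark]
  out_keys <- dplyr::distinct(
    tibble::tibble(image_id = out_led$image_id,
                   annotator_id = out_led$annotator_id,
                   landmark = out_led$review_landmark))
  pos$is_outlier <- vctrs_key(pos[c("image_id", "annotator_id", "landmark")]) %in%
    vctrs_key(out_keys)
  flags <- corrupted$image_flags
  pos$is_anomaly <- pos$image_id %in% flags$image_id[flags$anomaly] &
    pos$landmark %in% c("sacral_midpoint_cal", "sacral_midpoint_est")
  pos$is_badq <- pos$image_id %in% flags$image_id[flags$bad_quality]
  pos$reason <- ifelse(pos$is_outlier, "outlier",
                ifelse(pos$is_anomaly, "anomaly",
                ifelse(pos$is_badq, "bad_quality", "other")))
  pos <- dplyr::arrange(pos, .data$image_id, .data$landmark,
                        .data$annotator_id)

  all_keys <- dplyr::distinct(pos, .data$image_id, .data$landmark)
  ratings <- vector("list", n_assessors)
  for (j in seq_len(n_assessors)) {
    assessor <- sprintf("assessor%d", j)
    flip <- stats::runif(nrow(pos)) < model$assessor_error_prob
    final <- xor(pos$base_flag, flip)
    fl <- pos[final, c("image_id", "landmark", "annotator_id", "reason")]
    fl$reason[!pos$base_flag[final]] <- "other"
    fl$assessor_id <- assessor
    ok <- dplyr::anti_join(all_keys,
                           dplyr::distinct(fl, .data$image_id, .data$landmark),
                           by = c("image_id", "landmark"))
    ok$assessor_id <- assessor
    ok$annotator_id <- NA_character_
    ok$reason <- NA_character_
    ratings[[j]] <- dplyr::bind_rows(fl, ok)
  }
  r <- dplyr::bind_rows(ratings)
  if (nrow(r) == 0) return(empty_ratings())
  validate_ratings(r[, rating_cols])
}

vctrs_key <- function(df) {
  do.call(paste, c(as.list(df), sep = "\r"))
}

#' Simulate a complete annotation study
#'
#' Convenience wrapper chaining [generate_truth()], [corrupt()] and
#' [simulate_assessors()] with sub-seeds derived from `seed`.
#'
#' @inheritParams generate_truth
#' @inheritParams corrupt
#' @inheritParams simulate_assessors
#' @param noise A [noise_model()].
#' @param assessors An [assessor_model()].
#' @return A list with `truth` (truth table), `landmarks` (corrupted
#'   annotations), `ratings`, `ledger` and `image_flags`.
#' @export
simulate_study <- function(n_images = 115, template = pelvis_template(),
                           noise = noise_model(),
                           assessors = assessor_model(),
                           n_annotators = 5, n_assessors = 3,
                           pt_jitter_deg = 12, seed = 1) {
  truth <- generate_truth(template, n_images, pt_jitter_deg, seed = seed)
  corr <- corrupt(truth, n_annotators, noise, seed = seed + 1L)
  ratings <- simulate_assessors(corr, truth, assessors, n_assessors,
                                seed = seed + 2L)
  list(truth = truth$truth, truth_landmarks = truth$landmarks,
       landmarks = corr$landmarks, ratings = ratings,
       ledger = corr$ledger, image_flags = corr$image_flags)
}
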