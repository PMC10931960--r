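quiet_noise <- function(sigma_px = 0, ...) {
  noise_model(sigma_px = sigma_px, outlier_prob = 0,
              bad_quality_image_prob = 0, anomaly_image_prob = 0, ...)
}

test_that("truth generation is deterministic and jitter-free when asked", {
  tpl <- pelvis_template()
  a <- generate_truth(tpl, 6, pt_jitter_deg = 10, seed = 2)
  b <- generate_truth(tpl, 6, pt_jitter_deg = 10, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, generate_truth(tpl, 6, pt_jitter_deg = 10,
                                           seed = 3)))

  still <- generate_truth(tpl, 4, pt_jitter_deg = 0, seed = 1)
  expect_true(all(still$truth$true_pt_m_deg == tpl$true_pt_m))
  coords <- split(still$landmarks[, c("landmark", "point_index", "x", "y")],
                  still$landmarks$image_id)
  for (i in seq_along(coords)) {
    expect_equal(coords[[i]], coords[[1]], ignore_attr = TRUE)
  }
})

test_that("corruption with all mechanisms off is the identity", {
  tr <- generate_truth(pelvis_template(), 3, pt_jitter_deg = 5, seed = 9)
  co <- corrupt(tr, n_annotators = 2, quiet_noise(), seed = 4)
  expect_equal(nrow(co$ledger), 0)
  for (ann in c("ann1", "ann2")) {
    sub <- co$landmarks[co$landmarks$annotator_id == ann, ]
    sub$annotator_id <- "truth"
    expect_equal(dplyr::arrange(sub, image_id, landmark, point_index),
                 dplyr::arrange(tr$landmarks, image_id, landmark, point_index))
  }
})

test_that("corruption is reproducible under a fixed seed", {
  tr <- generate_truth(pelvis_template(), 10, pt_jitter_deg = 8, seed = 5)
  a <- corrupt(tr, 5, noise_model(), seed = 11)
  b <- corrupt(tr, 5, noise_model(), seed = 11)
  expect_identical(a, b)
})

test_that("per-point jitter has the requested RMS magnitude", {
  tr <- generate_truth(pelvis_template(), 200, pt_jitter_deg = 0, seed = 13)
  co <- corrupt(tr, 5, quiet_noise(sigma_px = 1), seed = 14)
  truth_xy <- dplyr::arrange(tr$landmarks, image_id, landmark, point_index)
  dev2 <- unlist(lapply(paste0("ann", 1:5), function(ann) {
    sub <- co$landmarks[co$landmarks$annotator_id == ann, ]
    sub <- dplyr::arrange(sub, image_id, landmark, point_index)
    c((sub$x - truth_xy$x)^2, (sub$y - truth_xy$y)^2)
  }))
  rms <- sqrt(mean(dev2))  # per-coordinate RMS should approach sigma = 1
  expect_lt(abs(rms - 1), 0.05)
})

test_that("injected outliers are flagged by all perfect assessors and excluded", {
  tr <- generate_truth(pelvis_template(), 2, pt_jitter_deg = 0, seed = 3)
  co <- corrupt(tr, 5, quiet_noise(), seed = 3)
  # displace ann5's estimated sacral midpoint on img0001 by 40 px
  hit <- co$landmarks$annotator_id == "ann5" &
    co$landmarks$image_id == "img0001" &
    co$landmarks$landmark == "sacral_midpoint_est"
  co$landmarks$x[hit] <- co$landmarks$x[hit] + 40
  co$ledger <- tibble::tibble(
    image_id = "img0001", annotator_id = "ann5",
    landmark = "sacral_midpoint_est", type = "outlier",
    shift_x = 40, shift_y = 0, magnitude = 40)

  ratings <- simulate_assessors(co, tr, assessor_model(flag_threshold_px = 15,
                                                       assessor_error_prob = 0),
                                n_assessors = 3, seed = 6)
  fl <- ratings[!is.na(ratings$annotator_id), ]
  expect_equal(nrow(fl), 3)
  expect_true(all(fl$annotator_id == "ann5" & fl$reason == "outlier" &
                  fl$landmark == "sacral_midpoint_est" &
                  fl$image_id == "img0001"))

  res <- resolve_adequacy(ratings)
  mask <- exclusion_mask(res)
  expect_equal(mask$annotator_id, "ann5")
  expect_equal(mask$method, "estimation")
})

test_that("clean studies draw no flags from perfect assessors", {
  tr <- generate_truth(pelvis_template(), 4, pt_jitter_deg = 5, seed = 8)
  co <- corrupt(tr, 5, quiet_noise(sigma_px = 0.5), seed = 9)
  ratings <- simulate_assessors(co, tr,
                                assessor_model(flag_threshold_px = 15,
                                               assessor_error_prob = 0),
                                seed = 10)
  expect_true(all(is.na(ratings$annotator_id)))
  expect_equal(nrow(ratings), 4 * 6 * 3)
})

test_that("certain assessor error inverts every verdict of the error-free run", {
  tr <- generate_truth(pelvis_template(), 3, pt_jitter_deg = 0, seed = 2)
  co <- corrupt(tr, 3, noise_model(), seed = 21)
  clean <- simulate_assessors(co, tr, assessor_model(assessor_error_prob = 0),
                              seed = 31)
  flipped <- simulate_assessors(co, tr, assessor_model(assessor_error_prob = 1),
                                seed = 31)
  key <- function(r) {
    f <- r[!is.na(r$annotator_id), ]
    sort(paste(f$image_id, f$assessor_id, f$landmark, f$annotator_id))
  }
  # every (image, assessor, landmark, annotator) flag state is complemented
  grid <- tidyr::expand_grid(image_id = sprintf("img%04d", 1:3),
                             assessor_id = paste0("assessor", 1:3),
                             landmark = pt_review_landmarks(),
                             annotator_id = paste0("ann", 1:3))
  universe <- sort(paste(grid$image_id, grid$assessor_id, grid$landmark,
                         grid$annotator_id))
  expect_setequal(c(key(clean), key(flipped)), universe)
  expect_length(intersect(key(clean), key(flipped)), 0)
})

test_that("bad-quality and anomaly images are ledgered and reason-attributed", {
  tr <- generate_truth(pelvis_template(), 30, pt_jitter_deg = 0, seed = 4)
  nm <- noise_model(sigma_px = 0.5, outlier_prob = 0,
                    bad_quality_image_prob = 0.3,
                    bad_quality_sigma_multiplier = 40,
                    anomaly_image_prob = 0.3,
                    anomaly_endplate_offset_px = 50)
  co <- corrupt(tr, 5, nm, seed = 7)
  expect_true(any(co$image_flags$bad_quality))
  expect_true(any(co$image_flags$anomaly))
  expect_setequal(unique(co$ledger$type), c("bad_quality", "anomaly"))

  ratings <- simulate_assessors(co, tr,
                                assessor_model(flag_threshold_px = 15,
                                               assessor_error_prob = 0),
                                seed = 8)
  fl <- ratings[!is.na(ratings$annotator_id), ]
  anom_imgs <- co$image_flags$image_id[co$image_flags$anomaly]
  anom_flags <- fl[fl$reason == "anomaly", ]
  expect_gt(nrow(anom_flags), 0)
  expect_true(all(anom_flags$image_id %in% anom_imgs))
  expect_true(all(anom_flags$landmark %in%
                  c("sacral_midpoint_cal", "sacral_midpoint_est")))
  badq_flags <- fl[fl$reason == "bad_quality", ]
  expect_gt(nrow(badq_flags), 0)
  expect_true(all(badq_flags$image_id %in%
                  co$image_flags$image_id[co$image_flags$bad_quality]))
})

test_that("model constructors validate their parameters", {
  expect_error(noise_model(sigma_px = -1))
  expect_error(noise_model(outlier_prob = 1.4))
  expect_error(noise_model(outlier_prob = c(elbow = 0.1)), "unknown landmark")
  expect_error(assessor_model(flag_threshold_px = 0))
  expect_error(assessor_model(assessor_error_prob = 2))
  expect_error(pelvis_template(true_pt_m = 95))
})
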