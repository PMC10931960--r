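flag_row <- function(image_id, assessor_id, landmark, annotator_id, reason) {
  tibble::tibble(image_id = image_id, assessor_id = assessor_id,
                 landmark = landmark, annotator_id = annotator_id,
                 reason = reason)
}

test_that("majority resolution evaluates its three clauses independently", {
  # two assessors flag the same annotator: inadequate, reason majority,
  # annotation excluded
  r1 <- build_ratings(
    rbind(flag_row("img1", "assessor1", "asis_centre", "ann5", "outlier"),
          flag_row("img1", "assessor2", "asis_centre", "ann5", "outlier")),
    "img1")
  out1 <- resolve_adequacy(r1)
  row1 <- out1[out1$landmark == "asis_centre", ]
  expect_true(row1$landmark_inadequate)
  expect_equal(row1$reasons_majority[[1]], "outlier")
  expect_equal(row1$excluded_annotations[[1]], "ann5")

  # two assessors flag different annotators for different reasons:
  # landmark-wise majority holds, but no reason or annotator majority
  r2 <- build_ratings(
    rbind(flag_row("img1", "assessor1", "asis_centre", "ann5", "outlier"),
          flag_row("img1", "assessor2", "asis_centre", "ann2", "bad_quality")),
    "img1")
  row2 <- resolve_adequacy(r2)
  row2 <- row2[row2$landmark == "asis_centre", ]
  expect_true(row2$landmark_inadequate)
  expect_length(row2$reasons_majority[[1]], 0)
  expect_length(row2$excluded_annotations[[1]], 0)

  # a single assessor is not a majority
  r3 <- build_ratings(
    flag_row("img1", "assessor1", "asis_centre", "ann5", "outlier"), "img1")
  row3 <- resolve_adequacy(r3)
  row3 <- row3[row3$landmark == "asis_centre", ]
  expect_false(row3$landmark_inadequate)
  expect_length(row3$excluded_annotations[[1]], 0)

  # same reason cited by two assessors for *different* annotators still
  # reaches the reason majority without excluding anyone
  r4 <- build_ratings(
    rbind(flag_row("img1", "assessor1", "sacral_midpoint_est", "ann1", "anomaly"),
          flag_row("img1", "assessor2", "sacral_midpoint_est", "ann4", "anomaly")),
    "img1")
  row4 <- resolve_adequacy(r4)
  row4 <- row4[row4$landmark == "sacral_midpoint_est", ]
  expect_equal(row4$reasons_majority[[1]], "anomaly")
  expect_length(row4$excluded_annotations[[1]], 0)
})

test_that("resolution is invariant to assessor and annotator relabelling", {
  flags <- rbind(
    flag_row("img1", "assessor1", "asis_centre", "ann5", "outlier"),
    flag_row("img1", "assessor2", "asis_centre", "ann5", "outlier"),
    flag_row("img1", "assessor2", "asis_centre", "ann3", "bad_quality"),
    flag_row("img1", "assessor3", "asis_centre", "ann3", "bad_quality"))
  base <- resolve_adequacy(build_ratings(flags, "img1"))

  swap <- flags
  swap$assessor_id <- c("assessor3", "assessor1", "assessor1", "assessor2")
  swapped <- resolve_adequacy(build_ratings(swap, "img1"))
  expect_equal(swapped$landmark_inadequate, base$landmark_inadequate)
  expect_equal(swapped$reasons_majority, base$reasons_majority)
  expect_equal(swapped$excluded_annotations, base$excluded_annotations)

  perm <- flags[c(3, 1, 4, 2), ]
  expect_equal(resolve_adequacy(build_ratings(perm, "img1")), base)
})

test_that("incomplete assessor coverage is an error naming the key", {
  r <- build_ratings(tibble::tibble(), "img1",
                     assessor_ids = c("assessor1", "assessor2"))
  expect_error(resolve_adequacy(r), "img1.*2 assessor.*expected 3")
})

test_that("configurable majority threshold k is honoured", {
  flags <- rbind(
    flag_row("img1", "assessor1", "asis_centre", "ann5", "outlier"),
    flag_row("img1", "assessor2", "asis_centre", "ann5", "outlier"))
  r <- build_ratings(flags, "img1")
  strict <- resolve_adequacy(r, k = 3)
  expect_false(strict$landmark_inadequate[strict$landmark == "asis_centre"])
  lax <- resolve_adequacy(r, k = 1)
  expect_true(lax$landmark_inadequate[lax$landmark == "asis_centre"])
})

test_that("landmark-wise table counts images and the any-landmark union", {
  res <- resolve_adequacy(build_ratings(rbind(
    flag_row("img1", "assessor1", "asis_centre", "ann1", "outlier"),
    flag_row("img1", "assessor2", "asis_centre", "ann1", "outlier"),
    flag_row("img1", "assessor1", "pubic_tubercle", "ann2", "bad_quality"),
    flag_row("img1", "assessor3", "pubic_tubercle", "ann4", "bad_quality"),
    flag_row("img2", "assessor2", "asis_centre", "ann3", "other"),
    flag_row("img2", "assessor3", "asis_centre", "ann3", "other")),
    c("img1", "img2", "img3")))
  t1 <- tabulate_landmark_wise(res, 3)
  expect_equal(t1$cases[t1$landmark == "asis_centre"], 2L)
  expect_equal(t1$cases[t1$landmark == "pubic_tubercle"], 1L)
  expect_equal(t1$cases[t1$landmark == "any_landmark"], 2L)
  expect_gte(t1$cases[t1$landmark == "any_landmark"],
             max(t1$cases[t1$landmark != "any_landmark"]))
  expect_equal(t1$percentage[t1$landmark == "any_landmark"], 66.67)

  clean <- resolve_adequacy(build_ratings(tibble::tibble(), c("img1", "img2")))
  t0 <- tabulate_landmark_wise(clean, 2)
  expect_true(all(t0$cases == 0) && all(t0$percentage == 0))
  expect_error(tabulate_landmark_wise(clean, 0), "positive")
})

test_that("reason-wise table covers the full landmark-reason grid", {
  clean <- resolve_adequacy(build_ratings(tibble::tibble(), "img1"))
  t2 <- tabulate_reason_wise(clean, 1)
  expect_equal(nrow(t2), 6 * 4)
  expect_true(all(t2$cases == 0))
  expect_true(all(t2$cases >= 0))
})

test_that("exclusions map to the single parameter variant they invalidate", {
  res <- resolve_adequacy(build_ratings(rbind(
    flag_row("img7", "assessor1", "sacral_midpoint_est", "ann5", "outlier"),
    flag_row("img7", "assessor3", "sacral_midpoint_est", "ann5", "outlier")),
    "img7"))
  mask <- exclusion_mask(res)
  expect_equal(nrow(mask), 1)
  expect_equal(mask$definition, "PT_m")
  expect_equal(mask$method, "estimation")
  expect_equal(nrow(mask), sum(lengths(res$excluded_annotations)))

  # the estimation measurement disappears, the calculation one survives
  meas <- tibble::tibble(
    image_id = "img7", annotator_id = "ann5",
    definition = c("PT_m", "PT_m"),
    method = c("calculation", "estimation"),
    angle_deg = c(10, 11))
  kept <- case_average(meas, mask)
  expect_equal(kept$parameter, "PT_m_cal")

  empty <- exclusion_mask(resolve_adequacy(
    build_ratings(tibble::tibble(), "img7")))
  expect_equal(nrow(empty), 0)
})

test_that("rating validation enforces the flag schema", {
  expect_error(validate_ratings(tibble::tibble(image_id = "i")),
               "missing column")
  expect_error(validate_ratings(
    flag_row("img1", "assessor1", "asis_centre", "ann1", NA)),
    "carry a reason")
  expect_error(validate_ratings(
    flag_row("img1", "assessor1", "asis_centre", NA, "outlier")),
    "all-satisfactory")
  expect_error(validate_ratings(rbind(
    flag_row("img1", "assessor1", "asis_centre", "ann1", "outlier"),
    flag_row("img1", "assessor1", "asis_centre", "ann1", "bad_quality"))),
    "more than once")
  expect_error(validate_ratings(
    flag_row("img1", "assessor1", "femoral_head_1_contour", "ann1", "outlier")),
    "unknown review landmark")
})

test_that("rating tables round trip through csv and json", {
  r <- build_ratings(rbind(
    flag_row("img1", "assessor1", "asis_centre", "ann5", "outlier"),
    flag_row("img1", "assessor2", "sacral_midpoint_cal", "ann2", "anomaly")),
    c("img1", "img2"))
  r <- validate_ratings(r)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ratings(r, csv, "csv")
  expect_equal(read_ratings(csv, "csv"), r)
  js <- withr::local_tempfile(fileext = ".json")
  write_ratings(r, js, "json")
  expect_equal(read_ratings(js, "json"), r)
})
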