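test_that("five tips and four valleys are found, alternating along the boundary", {
  pipe <- pipeline_clean()
  lm <- pipe$landmarks
  expect_equal(nrow(lm$tips), 5L)
  expect_equal(nrow(lm$valleys), 4L)
  idx <- sort(c(lm$tip_idx, lm$valley_idx))
  is_tip <- idx %in% lm$tip_idx
  expect_true(all(is_tip == rep(c(TRUE, FALSE), length.out = 9)) ||
              all(is_tip == rep(c(FALSE, TRUE), length.out = 9)))
})

test_that("detected tips fall within 2 mm of ground truth, valleys close by", {
  r <- scene_bent()
  lm <- pipeline_bent()$landmarks
  gt <- r$ground_truth
  expect_lt(max(sqrt(rowSums((lm$tips - gt$tips_mm)^2))), 2)
  expect_lt(max(sqrt(rowSums((lm$valleys - gt$valleys_mm)^2))), 3)
  expect_equal(lm$handedness, "right")
})

test_that("landmarks are equivariant to scene rotation (compared in the paper frame)", {
  lm0 <- pipeline_clean()$landmarks
  lm90 <- pipeline_rot90()$landmarks
  expect_lt(max(sqrt(rowSums((lm0$tips - lm90$tips)^2))), 1)
  expect_lt(max(sqrt(rowSums((lm0$valleys - lm90$valleys)^2))), 1)
})

test_that("a mirrored (left) hand mirrors landmark positions and handedness", {
  r <- scene_left()
  pipe <- run_pipeline(r)
  lm <- pipe$landmarks
  expect_equal(lm$handedness, "left")
  gt <- r$ground_truth
  expect_lt(max(sqrt(rowSums((lm$tips - gt$tips_mm)^2))), 2)
  # mirror of the right-hand ground truth about the paper midline
  rgt <- scene_bent()$ground_truth$hand
  geomR <- handmetry:::build_hand_geometry(rgt)
  mirrored <- geomR$fingers$middle$apex; mirrored[1] <- 215.9 - mirrored[1]
  expect_lt(sqrt(sum((lm$tips["middle", ] - mirrored)^2)), 2)
})

test_that("touching fingers are reported as not spread", {
  h <- default_hand_spec()
  h$fingers$ring$spread_deg <- -6
  r <- render_scene(h, scene_spec(px_per_mm = 5, noise_sd = 0, seed = 9),
                    validate = FALSE, gt_landmarks = FALSE)
  cal <- compute_calibration(detect_paper_quad(r$image))
  b <- extract_boundary(segment_hand(r$image, cal))
  expect_handmetry_error(detect_fingertips_valleys(b), "fingers_not_spread")
})

test_that("centerlines stay inside the silhouette and track straight fingers", {
  pipe <- pipeline_clean()
  axes <- finger_axes(pipe$boundary, pipe$landmarks)
  for (fn in names(axes)) {
    cl <- axes[[fn]]$centerline
    interior <- cl[3:(nrow(cl) - 2), , drop = FALSE]
    expect_true(all(handmetry:::points_in_polygon(interior, pipe$boundary$xy)),
                info = fn)
  }
  # straight capsule: lateral deviation of the centerline from the
  # tip-to-base line under 0.5 mm
  cl <- axes$middle$centerline
  a <- cl[1, ]; b <- cl[nrow(cl), ]
  e <- (b - a) / sqrt(sum((b - a)^2))
  lat <- abs((cl[, 1] - a[1]) * -e[2] + (cl[, 2] - a[2]) * e[1])
  expect_lt(max(lat), 0.5)
})

test_that("an imposed PIP bend shows up as one centerline direction change", {
  r <- scene_bent()      # middle PIP deviation 12 degrees
  pipe <- pipeline_bent()
  axes <- finger_axes(pipe$boundary, pipe$landmarks)
  cl <- axes$middle$centerline
  arc <- handmetry:::polyline_arc(cl)
  L <- arc[length(arc)]
  d_dist <- handmetry:::segment_direction(cl, arc, 0.30 * L, 0.55 * L)
  d_prox <- handmetry:::segment_direction(cl, arc, 0.60 * L, L)
  bend <- handmetry:::vec_angle_deg(d_prox, d_dist)
  expect_lt(abs(bend - 12), 2)
})
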