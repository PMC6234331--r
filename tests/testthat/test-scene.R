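test_that("identity pose at 10 px/mm puts paper corners on the canonical rectangle", {
  sc <- scene_spec(px_per_mm = 10, translation_px = c(0, 0),
                   image_size_px = c(2159, 2794), blur_sigma_px = 0)
  r <- render_scene(default_hand_spec(), sc, gt_landmarks = FALSE)
  expect_equal(unname(r$ground_truth$corners_px),
               rbind(c(0, 0), c(2159, 0), c(2159, 2794), c(0, 2794)),
               tolerance = 1e-12)
})

test_that("renders are bit-identical for a fixed seed", {
  sc <- scene_spec(px_per_mm = 4, rotation_deg = 17, noise_sd = 4 / 255, seed = 11)
  r1 <- render_scene(default_hand_spec(), sc, gt_landmarks = FALSE)
  r2 <- render_scene(default_hand_spec(), sc, gt_landmarks = FALSE)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$ground_truth, r2$ground_truth)
})

test_that("rendered silhouette width matches the spec at a known cross-section", {
  # index PIP width 18 mm at 10 px/mm, no noise: expect 180 +/- 2 px along
  # the true perpendicular cross-section in the unwarped raster
  h <- default_hand_spec()
  h$fingers$index$widths_mm["pip"] <- 18
  sc <- scene_spec(px_per_mm = 10, translation_px = c(0, 0),
                   image_size_px = c(2159, 2794), noise_sd = 0, blur_sigma_px = 0)
  r <- render_scene(h, sc, gt_landmarks = FALSE)
  geom <- handmetry:::build_hand_geometry(h)
  f <- geom$fingers$index
  pip_mm <- f$chain[2, ]                      # proximal/middle junction
  dirs <- f$dirs[2, ]                         # middle-segment direction
  nrm <- c(-dirs[2], dirs[1])
  ts <- seq(-15, 15, by = 0.01)               # mm, 0.01 mm sampling
  pts_px <- cbind((pip_mm[1] + ts * nrm[1]) * 10, (pip_mm[2] + ts * nrm[2]) * 10)
  v <- handmetry:::bilinear_sample(r$image, pts_px)
  dark <- v < (0.85 + 0.45) / 2
  width_px <- sum(dark) * 0.01 * 10
  expect_lt(abs(width_px - 180), 2)
})

test_that("invalid hands are rejected by the renderer", {
  h <- default_hand_spec()
  h$fingers$ring$spread_deg <- -6   # converges onto the middle finger
  expect_handmetry_error(render_scene(h, scene_spec(seed = 1)), "fingers_touching")

  h2 <- default_hand_spec()
  h2$fingers$thumb$spread_deg <- -70                         # runs off the sheet
  expect_handmetry_error(render_scene(h2, scene_spec(seed = 1)), "hand_outside_margin")
})

test_that("ground-truth mm landmarks map to px landmarks through the pose", {
  r <- scene_rot30()
  gt <- r$ground_truth
  px <- handmetry:::apply_homography(gt$pose, gt$tips_mm)
  expect_lt(max(abs(px - gt$tips_px)), 0.1)
  pxc <- handmetry:::apply_homography(gt$pose, gt$corners_mm)
  expect_lt(max(abs(pxc - gt$corners_px)), 0.1)
})

test_that("rendered silhouette area agrees with the hand model area", {
  r <- scene_clean()
  img <- r$image
  gt <- r$ground_truth
  # hand pixels inside the paper rectangle (the wrist continues over the
  # background beyond the bottom edge; the model raster is clipped there)
  nx <- nrow(img); ny <- ncol(img)
  pts <- cbind(rep(seq_len(nx) - 0.5, times = ny),
               rep(seq_len(ny) - 0.5, each = nx))
  mm <- px_to_mm(gt$calibration, pts)
  on_paper <- mm[, 1] >= 0 & mm[, 1] <= 215.9 & mm[, 2] >= 0 & mm[, 2] <= 279.4
  dark <- as.vector(img) < (0.85 + 0.45) / 2
  mm_area_px <- sum(dark & on_paper) / 5^2
  fine <- hand_silhouette_mask(gt$hand, res = 10)
  model_area <- sum(fine) / 10^2
  expect_lt(abs(mm_area_px - model_area) / model_area, 0.02)
})

test_that("a scene writes a PNG with its ground-truth side-car", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.png")
  write_scene(scene_clean(), p)
  expect_true(file.exists(p))
  expect_true(file.exists(sub("\\.png$", ".json", p)))
  gt <- jsonlite::fromJSON(sub("\\.png$", ".json", p))
  expect_equal(dim(gt$corners_px), c(4L, 2L))
})
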