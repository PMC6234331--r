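test_that("segmentation overlaps the true silhouette with Jaccard >= 0.98", {
  r <- scene_clean()
  pipe <- pipeline_clean()
  truth <- hand_silhouette_mask(r$ground_truth$hand,
                                res = pipe$mask$res,
                                offset = r$ground_truth$hand_offset_mm)
  inter <- sum(pipe$mask$mask & truth)
  union <- sum(pipe$mask$mask | truth)
  expect_gte(inter / union, 0.98)
})

test_that("an empty sheet raises NoHandFound", {
  img <- paper_only_image()
  cal <- compute_calibration(detect_paper_quad(img))
  expect_handmetry_error(segment_hand(img, cal), "no_hand_found")
})

test_that("small clutter on the paper is removed, leaving one component", {
  r <- scene_clean()
  img <- r$image
  # paint a 2 x 2 mm dark speck on open paper (30, 200) mm at 5 px/mm + margin
  px <- mm_to_px(r$ground_truth$calibration, c(30, 200))
  ix <- round(px[1]) + (-5:5); iy <- round(px[2]) + (-5:5)
  img[ix, iy] <- 0.2
  cal <- compute_calibration(detect_paper_quad(img))
  mask <- segment_hand(img, cal)
  lab <- EBImage::bwlabel(EBImage::Image(mask$mask * 1))
  expect_equal(max(lab), 1)
  # and the speck region is background in the final mask
  mm_speck <- round(c(30, 200) * mask$res)
  expect_false(any(mask$mask[mm_speck[1] + (-3:3), mm_speck[2] + (-3:3)]))
})

test_that("boundary of a disk mask reproduces the closed-form perimeter and area", {
  res <- 5; r_mm <- 30
  nx <- round(215.9 * res); ny <- round(279.4 * res)
  xs <- (seq_len(nx) - 0.5) / res; ys <- (seq_len(ny) - 0.5) / res
  disk <- outer(xs, ys, function(x, y) (x - 100)^2 + (y - 140)^2 <= r_mm^2)
  b <- extract_boundary(list(mask = disk, res = res))
  expect_lt(abs(b$perimeter_mm - 2 * pi * r_mm) / (2 * pi * r_mm), 0.01)
  expect_lt(abs(b$area_mm2 - pi * r_mm^2) / (pi * r_mm^2), 0.02)
  expect_null(b$wrist_chord)
  expect_gte(nrow(b$xy), 200)
})

test_that("square mask corners survive the boundary smoothing", {
  res <- 5
  nx <- round(215.9 * res); ny <- round(279.4 * res)
  m <- matrix(FALSE, nx, ny)
  m[round(60 * res):round(140 * res), round(100 * res):round(180 * res)] <- TRUE
  b <- extract_boundary(list(mask = m, res = res))
  for (cx in c(60, 140)) for (cy in c(100, 180)) {
    d <- sqrt((b$xy[, 1] - cx)^2 + (b$xy[, 2] - cy)^2)
    expect_lt(min(d), 1.5)   # corner rounded by at most the smoothing scale
  }
})

test_that("boundary area equals mask area within 2% on an identity-pose scene", {
  pipe <- pipeline_clean()
  mask_area <- sum(pipe$mask$mask) / pipe$mask$res^2
  expect_lt(abs(pipe$boundary$area_mm2 - mask_area) / mask_area, 0.02)
})

test_that("segmentation is invariant to global brightness offsets of +/- 20/255", {
  r <- scene_clean()
  base <- segment_hand(r$image, r$ground_truth$calibration)
  for (off in c(-20, 20) / 255) {
    img <- pmin(pmax(r$image + off, 0), 1)
    m <- segment_hand(img, r$ground_truth$calibration)
    inter <- sum(m$mask & base$mask); union <- sum(m$mask | base$mask)
    expect_gte(inter / union, 0.995)
  }
})

test_that("boundary extraction is idempotent under re-rasterization", {
  pipe <- pipeline_clean()
  b1 <- pipe$boundary
  res <- pipe$mask$res
  m2 <- handmetry:::rasterize_polygon(b1$xy, res, round(215.9 * res), round(279.4 * res))
  b2 <- extract_boundary(list(mask = m2, res = res))
  expect_lt(handmetry:::hausdorff_points(b2$xy, b1$xy), 0.5)
})
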