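test_that("a clean scene file yields a fully populated, schema-valid report", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "scene.png")
  write_scene(scene_clean(), p)
  rep <- analyze_image(p, overlay = file.path(dir, "overlay.png"))
  expect_true(rep$capture_validation$valid)
  expect_null(rep$failure)
  expect_false(is.null(rep$calibration))
  expect_false(is.null(rep$measurements))
  expect_equal(rep$measurements$handedness, "right")
  expect_true(isTRUE(validate_report(rep)))
  expect_true(file.exists(file.path(dir, "overlay.png")))

  out <- file.path(dir, "rep.json")
  write_report(rep, out)
  back <- read_report(out)
  expect_equal(back$measurements$span_mm, rep$measurements$span_mm,
               tolerance = 1e-12)
  expect_equal(unlist(back$capture_validation$checks),
               unlist(rep$capture_validation$checks))
})

test_that("repeated analysis of the same file is identical", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "scene.png")
  write_scene(scene_clean(), p)
  r1 <- analyze_image(p)
  r2 <- analyze_image(p)
  expect_identical(r1, r2)   # timestamp comes from the file, not the clock
})

test_that("a cropped-corner image reports rule 1 and carries no measurements", {
  img <- scene_clean()$image
  img <- img[, 1:(ncol(img) - 120)]
  rep <- handmetry:::analyze_matrix(img, timestamp = as.POSIXct("2026-01-01", tz = "UTC"))
  expect_false(rep$capture_validation$checks$four_corners_visible)
  expect_false(rep$capture_validation$valid)
  expect_null(rep$measurements)
  expect_equal(rep$failure$stage, "detect_paper")
  expect_true(isTRUE(validate_report(rep)))
})

test_that("a prior record produces a change block with flags end-to-end", {
  m1 <- make_measurements()
  prior <- measurement_record("p7", as.POSIXct("2025-12-01", tz = "UTC"),
                              "right", m1)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "scene.png")
  write_scene(scene_clean(), p)
  rep <- analyze_image(p, prior = prior, patient_id = "p7")
  expect_false(is.null(rep$change))
  expect_true(is.character(rep$change$recommendations))
})

test_that("missing files raise an I/O error", {
  expect_handmetry_error(analyze_image("/nonexistent/img.png"), "io_error")
})

test_that("config hash changes when a threshold changes", {
  a <- handmetry_config()
  b <- handmetry_config(flags = list(swelling_mm = 1))
  expect_false(identical(handmetry:::config_hash(a), handmetry:::config_hash(b)))
  expect_identical(handmetry:::config_hash(a),
                   handmetry:::config_hash(handmetry_config()))
})

test_that("yaml config overrides merge recursively", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cfg.yml")
  writeLines("flags:\n  swelling_mm: 1.5\n", f)
  cfg <- handmetry_config(file = f)
  expect_equal(cfg$flags$swelling_mm, 1.5)
  expect_equal(cfg$flags$deviation_deg, 3)     # untouched default
  expect_equal(cfg$segmentation$work_res_px_per_mm, 5)
})
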