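rec_at <- function(m, when, id = "p1", side = "right")
  measurement_record(id, as.POSIXct(when, tz = "UTC"), side, m)

test_that("identical records give zero deltas and no flags", {
  m <- make_measurements()
  cr <- compare_records(rec_at(m, "2026-01-01"), rec_at(m, "2026-02-01"))
  expect_true(all(cr$deltas$delta == 0))
  expect_length(cr$flags, 0)
  expect_identical(cr$recommendations, "NO_CHANGE")
})

test_that("a +2.5 mm PIP thickness increase flags exactly that joint", {
  m1 <- make_measurements()
  m2 <- make_measurements(thick_shift = c(middle_pip = 2.5))
  cr <- compare_records(rec_at(m1, "2026-01-01"), rec_at(m2, "2026-02-01"))
  expect_length(cr$flags, 1)
  expect_equal(cr$flags[[1]]$type, "SWELLING_SUSPECTED")
  expect_equal(cr$flags[[1]]$finger, "middle")
  expect_equal(cr$flags[[1]]$joint, "PIP")
  expect_equal(cr$flags[[1]]$delta_mm, 2.5)
  expect_true("RECHECK_SOON" %in% cr$recommendations)
})

test_that("deviation progression of 3 degrees or more is flagged", {
  m1 <- make_measurements()
  m2 <- make_measurements(dev_shift = c(index_pip = -4))  # |dev| grew by 4
  cr <- compare_records(rec_at(m1, "2026-01-01"), rec_at(m2, "2026-02-01"))
  types <- vapply(cr$flags, function(f) f$type, "")
  expect_true("DEVIATION_PROGRESSION" %in% types)
  expect_true("DISCUSS_WITH_CLINICIAN" %in% cr$recommendations)
})

test_that("deltas are antisymmetric under record exchange", {
  m1 <- make_measurements()
  m2 <- make_measurements(thick_shift = c(ring_dip = 1.2, little_pip = -0.7))
  a <- compare_records(rec_at(m1, "2026-01-01"), rec_at(m2, "2026-02-01"))
  b <- compare_records(rec_at(m2, "2026-02-01"), rec_at(m1, "2026-01-01"),
                       force = TRUE)
  m <- merge(a$deltas, b$deltas, by = "metric")
  expect_equal(m$delta.x, -m$delta.y, tolerance = 1e-12)
})

test_that("increasing a thickness delta never clears a swelling flag", {
  m1 <- make_measurements()
  has_flag <- function(d) {
    m2 <- make_measurements(thick_shift = c(middle_pip = d))
    cr <- compare_records(rec_at(m1, "2026-01-01"), rec_at(m2, "2026-02-01"))
    any(vapply(cr$flags, function(f) f$type == "SWELLING_SUSPECTED", TRUE))
  }
  flags <- vapply(seq(0, 6, by = 0.5), has_flag, TRUE)
  expect_true(all(diff(as.integer(flags)) >= 0))
  expect_false(flags[1]); expect_true(flags[length(flags)])
})

test_that("ordering and side/patient mismatches are rejected", {
  m <- make_measurements()
  expect_handmetry_error(
    compare_records(rec_at(m, "2026-02-01"), rec_at(m, "2026-01-01")),
    "order_violation")
  expect_handmetry_error(
    compare_records(rec_at(m, "2026-01-01", side = "left"),
                    rec_at(m, "2026-02-01", side = "right")),
    "side_mismatch")
  expect_handmetry_error(
    compare_records(rec_at(m, "2026-01-01", id = "a"),
                    rec_at(m, "2026-02-01", id = "b")),
    "side_mismatch")
})

test_that("flags require valid captures on both sides", {
  m1 <- make_measurements()
  m2 <- make_measurements(thick_shift = c(middle_pip = 3))
  bad <- structure(list(checks = c(four_corners_visible = FALSE), valid = FALSE),
                   class = "capture_validation")
  r2 <- measurement_record("p1", as.POSIXct("2026-02-01", tz = "UTC"), "right",
                           m2, validation = bad)
  cr <- compare_records(rec_at(m1, "2026-01-01"), r2)
  expect_length(cr$flags, 0)
})

test_that("series trends recover a linear drift and degrade gracefully", {
  base <- make_measurements()
  recs <- lapply(0:5, function(k) {
    m <- make_measurements(thick_shift = c(middle_pip = 1 * k))  # +1 mm / month
    rec_at(m, sprintf("2026-%02d-01", k + 1))
  })
  # months are 30.44 days; calendar months drift slightly, allow 5%
  tr <- series_trend(recs)
  s <- tr$slope_per_month[tr$metric == "middle.thickness_pip_mm"]
  expect_lt(abs(s - 1) / 1, 0.05)
  s0 <- tr$slope_per_month[tr$metric == "ring.thickness_dip_mm"]
  expect_lt(abs(s0), 1e-9)
  expect_equal(nrow(series_trend(recs[1])), 0)
})

test_that("records round-trip through the JSON-lines store", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "p1.jsonl")
  r1 <- rec_at(make_measurements(), "2026-01-01")
  r2 <- rec_at(make_measurements(thick_shift = c(middle_pip = 2.5)), "2026-02-01")
  write_record(r1, p); write_record(r2, p)
  back <- read_records(p)
  expect_length(back, 2)
  cr <- compare_records(back[[1]], back[[2]])
  expect_equal(cr$flags[[1]]$delta_mm, 2.5, tolerance = 1e-9)
})
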