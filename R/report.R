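# End-to-end orchestration: image file -> capture validation ->
# calibration -> segmentation -> landmarks -> measurements
# (-> comparison against a prior record), assembled into a serializable
# analysis report with an optional annotated overlay image.

REPORT_SCHEMA_VERSION <- "1.0"

#' Analyze a hand photograph
#'
#' Runs the full pipeline on an image file.  A failure at any stage
#' produces a report describing the failed stage and the capture
#' validation state instead of an error; only unreadable input raises.
#'
#' @param path PNG/JPEG/TIFF image file.
#' @param config A [handmetry_config()].
#' @param prior Optional earlier `measurement_record` for the change
#'   block.
#' @param patient_id,side Identifiers stored in the report and used for
#'   the comparison.
#' @param timestamp Capture time (default: file modification time, so
#'   repeated analyses of one file agree).
#' @param overlay Optional path; writes a PNG with the detected corners,
#'   boundary and landmarks drawn in.
#' @return An `analysis_report` (nested list; see [write_report()]).
#' @export
analyze_image <- function(path, config = handmetry_config(), prior = NULL,
                          patient_id = "anonymous", side = NULL,
                          timestamp = NULL, overlay = NULL) {
  if (!file.exists(path)) hm_error("io_error", sprintf("file not found: %s", path))
  img <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                  error = function(e) hm_error("io_error",
                    sprintf("unreadable image %s: %s", path, conditionMessage(e))))
  if (is.null(timestamp)) timestamp <- file.info(path)$mtime
  analyze_matrix(img, config = config, prior = prior, patient_id = patient_id,
                 side = side, timestamp = timestamp, overlay = overlay,
                 source = path)
}

# Same pipeline on an in-memory image matrix (used by tests and the
# renderer round-trip).
analyze_matrix <- function(img, config = handmetry_config(), prior = NULL,
                           patient_id = "anonymous", side = NULL,
                           timestamp = Sys.time(), overlay = NULL,
                           source = "<matrix>") {
  stage <- "detect_paper"
  quad <- tryCatch(detect_paper_quad(img, config), handmetry_error = function(e) e)
  if (inherits(quad, "error")) quad <- NULL
  validation <- validate_capture(img, quad, config)

  cal <- NULL; mask <- NULL; boundary <- NULL; landmarks <- NULL
  measurements <- NULL; change <- NULL; failure <- NULL
  if (!is.null(quad)) {
    res <- tryCatch({
      stage <- "calibrate";  cal <- compute_calibration(quad)
      stage <- "segment";    mask <- segment_hand(img, cal, config)
      stage <- "boundary";   boundary <- extract_boundary(mask, config)
      stage <- "landmarks";  landmarks <- detect_fingertips_valleys(boundary, config)
      stage <- "measure";    measurements <- measure_hand(boundary, landmarks, cal, config)
      NULL
    }, handmetry_error = function(e) e)
    if (inherits(res, "error"))
      failure <- list(stage = stage, message = conditionMessage(res))
  } else failure <- list(stage = "detect_paper", message = "paper not found")

  if (!is.null(measurements) && is.null(side)) side <- measurements$handedness
  if (!is.null(measurements) && !is.null(prior)) {
    curr_rec <- measurement_record(patient_id, timestamp, side, measurements,
                                   validation)
    change <- tryCatch(compare_records(prior, curr_rec, config$flags),
                       handmetry_error = function(e)
                         list(error = conditionMessage(e)))
    if (inherits(change, "change_report")) change <- change_block(change)
  }

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    tool_version = as.character(utils::packageVersion("handmetry")),
    config_hash = config_hash(config),
    source = source,
    patient_id = patient_id,
    side = side,
    timestamp = format(as.POSIXct(timestamp, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ"),
    capture_validation = list(checks = as.list(validation$checks),
                              violations = validation$violations,
                              valid = validation$valid),
    calibration = if (is.null(cal)) NULL else list(
      scale_mm_per_px = cal$center_scale_mm_per_px,
      aspect_mismatch = cal$aspect_mismatch,
      corner_confidence = if (is.null(quad)) NULL else unname(quad$confidence),
      corners_px = if (is.null(quad)) NULL else unname(apply(quad$corners, 1, c, simplify = FALSE))),
    measurements = if (is.null(measurements)) NULL else measurements_block(measurements),
    change = change,
    failure = failure
  )
  class(report) <- c("analysis_report", "list")
  if (!is.null(overlay) && !is.null(boundary))
    write_overlay(img, quad, boundary, landmarks, cal, overlay)
  report
}

measurements_block <- function(m) {
  list(fingers = lapply(m$fingers, function(f) list(
         length_mm = f$length_mm,
         joint_arc_mm = as.list(f$joint_arc_mm),
         thickness_mm = as.list(f$thickness_mm),
         angulation_deg = as.list(f$angulation_deg),
         deviation_deg = as.list(f$deviation_deg),
         low_confidence = as.list(f$low_confidence))),
       palm_width_mm = m$palm_width_mm,
       span_mm = m$span_mm,
       handedness = m$handedness,
       scale_mm_per_px = m$scale_mm_per_px)
}

change_block <- function(cr) {
  list(from = format(cr$from, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       to = format(cr$to, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       deltas = cr$deltas, flags = cr$flags,
       recommendations = cr$recommendations)
}

#' Write / read an analysis report as JSON
#'
#' Round-trips losslessly (up to numeric precision) through JSON.
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `path` (write) / the report (read).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  class(r) <- c("analysis_report", "list")
  r
}

#' Check a report against the shipped schema
#'
#' Structural validation: required fields present with the right types.
#' The machine-readable schema ships at
#' `system.file("schema", "report-schema.json", package = "handmetry")`.
#'
#' @param report An `analysis_report` (or list read from JSON).
#' @return `TRUE`, or a character vector of problems.
#' @export
validate_report <- function(report) {
  problems <- character()
  need <- c("schema_version", "tool_version", "config_hash", "timestamp",
            "capture_validation")
  for (nm in need)
    if (is.null(report[[nm]])) problems <- c(problems, paste("missing field:", nm))
  cv <- report$capture_validation
  if (!is.null(cv)) {
    want <- c("four_corners_visible", "hand_within_edges", "fingers_spread",
              "background_darker_uncluttered")
    have <- names(cv$checks)
    for (nm in want)
      if (!nm %in% have) problems <- c(problems, paste("missing check:", nm))
  }
  if (isTRUE(cv$valid) && is.null(report$failure) && is.null(report$measurements))
    problems <- c(problems, "valid capture but no measurements and no failure stage")
  if (length(problems)) problems else TRUE
}

# Draw corners, boundary, landmarks and centerlines into a copy of the
# image and save it as PNG.
write_overlay <- function(img, quad, boundary, landmarks, cal, path) {
  img <- to_gray(img)
  ov <- array(rep(img, 3), dim = c(dim(img), 3))
  put <- function(px, channel, w = 1L) {
    px <- round(px + 0.5)
    ok <- px[, 1] >= 1 & px[, 1] <= nrow(img) & px[, 2] >= 1 & px[, 2] <= ncol(img)
    px <- px[ok, , drop = FALSE]
    for (ch in 1:3) {
      v <- as.numeric(ch == channel)
      ov[cbind(px[, 1], px[, 2], ch)] <<- v
    }
  }
  if (!is.null(boundary) && !is.null(cal))
    put(mm_to_px(cal, boundary$xy), 2)            # boundary in green
  if (!is.null(quad))
    for (i in 1:4) {
      a <- quad$corners[i, ]; b <- quad$corners[(i %% 4) + 1, ]
      t <- seq(0, 1, length.out = 400)
      put(cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])), 1)  # quad in red
    }
  if (!is.null(landmarks) && !is.null(cal)) {
    marks <- rbind(landmarks$tips, landmarks$valleys)
    px <- mm_to_px(cal, marks)
    for (i in seq_len(nrow(px))) {
      th <- seq(0, 2 * pi, length.out = 60)
      put(cbind(px[i, 1] + 4 * cos(th), px[i, 2] + 4 * sin(th)), 3)     # landmarks in blue
    }
  }
  EBImage::writeImage(EBImage::Image(ov, colormode = "Color"), path, type = "png")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s | capture %s\n", x$source,
              if (isTRUE(x$capture_validation$valid)) "valid" else "INVALID"))
  if (!is.null(x$failure))
    cat(sprintf("  failed at stage '%s': %s\n", x$failure$stage, x$failure$message))
  if (!is.null(x$measurements))
    cat(sprintf("  %s hand, span %.1f mm, scale %.4f mm/px\n",
                x$measurements$handedness, x$measurements$span_mm,
                x$measurements$scale_mm_per_px))
  if (!is.null(x$change))
    cat("  recommendations:", paste(x$change$recommendations, collapse = ", "), "\n")
  invisible(x)
}
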