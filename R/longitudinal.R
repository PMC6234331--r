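# Longitudinal comparison of measurement records: per-metric deltas,
# swelling / deviation-progression flags, recommendation codes, and
# per-metric trend slopes over a record series.

#' Create a measurement record
#'
#' @param patient_id Character patient identifier.
#' @param timestamp Date or POSIXct of the capture.
#' @param side `"left"` or `"right"`.
#' @param measurements A `hand_measurements` from [measure_hand()].
#' @param validation Optional `capture_validation`; records from invalid
#'   captures never trigger clinical flags.
#' @return A `measurement_record`.
#' @export
measurement_record <- function(patient_id, timestamp, side, measurements,
                               validation = NULL) {
  if (!side %in% c("left", "right")) hm_error("side_mismatch", "side must be left/right")
  valid <- is.null(validation) || isTRUE(validation$valid)
  structure(list(patient_id = patient_id,
                 timestamp = as.POSIXct(timestamp, tz = "UTC"),
                 side = side,
                 measurements = measurements,
                 capture_valid = valid),
            class = "measurement_record")
}

record_metrics <- function(rec) {
  df <- as.data.frame(rec$measurements)
  stats::setNames(df$value, paste(df$finger, df$metric, sep = "."))
}

#' Compare two measurement records
#'
#' Computes per-metric deltas (current minus previous) and percent
#' changes, flags suspected swelling at any joint whose thickness
#' increased by at least `thresholds$swelling_mm` (default +2 mm, both
#' captures valid), and deviation progression where |deviation| increased
#' by at least `thresholds$deviation_deg` (default 3 degrees).
#' Recommendation codes are machine-readable strings:
#' `NO_CHANGE`, `RECHECK_SOON` (any flag), `DISCUSS_WITH_CLINICIAN`
#' (two or more swollen joints, or deviation progression).
#'
#' @param prev,curr `measurement_record`s for the same patient and side,
#'   `prev` strictly earlier.
#' @param thresholds List with `swelling_mm` and `deviation_deg`.
#' @param force Skip the ordering check (used by symmetry tests).
#' @return A `change_report`.
#' @export
compare_records <- function(prev, curr,
                            thresholds = handmetry_config()$flags,
                            force = FALSE) {
  if (!identical(prev$patient_id, curr$patient_id))
    hm_error("side_mismatch", "records belong to different patients")
  if (!identical(prev$side, curr$side))
    hm_error("side_mismatch", sprintf("hand side differs: %s vs %s", prev$side, curr$side))
  if (!force && !(prev$timestamp < curr$timestamp))
    hm_error("order_violation", "prev record must be strictly earlier than curr")

  mp <- record_metrics(prev); mc <- record_metrics(curr)
  common <- intersect(names(mp), names(mc))
  delta <- mc[common] - mp[common]
  pct <- ifelse(abs(mp[common]) > 1e-9, 100 * delta / mp[common], NA_real_)
  tab <- data.frame(metric = common, previous = unname(mp[common]),
                    current = unname(mc[common]), delta = unname(delta),
                    percent = unname(pct), row.names = NULL)

  flags <- list()
  both_valid <- isTRUE(prev$capture_valid) && isTRUE(curr$capture_valid)
  for (fn in names(curr$measurements$fingers)) {
    fp <- prev$measurements$fingers[[fn]]; fc <- curr$measurements$fingers[[fn]]
    if (is.null(fp)) next
    for (jn in names(fc$thickness_mm)) {
      d <- fc$thickness_mm[[jn]] - fp$thickness_mm[[jn]]
      if (both_valid && is.finite(d) && d >= thresholds$swelling_mm)
        flags[[length(flags) + 1]] <- list(type = "SWELLING_SUSPECTED",
                                           finger = fn, joint = toupper(jn),
                                           delta_mm = unname(d))
      dv <- abs(fc$deviation_deg[[jn]]) - abs(fp$deviation_deg[[jn]])
      if (both_valid && is.finite(dv) && dv >= thresholds$deviation_deg)
        flags[[length(flags) + 1]] <- list(type = "DEVIATION_PROGRESSION",
                                           finger = fn, joint = toupper(jn),
                                           delta_deg = unname(dv))
    }
  }
  n_swell <- sum(vapply(flags, function(f) f$type == "SWELLING_SUSPECTED", TRUE))
  n_dev <- sum(vapply(flags, function(f) f$type == "DEVIATION_PROGRESSION", TRUE))
  rec_codes <- if (!length(flags)) "NO_CHANGE" else "RECHECK_SOON"
  if (n_swell >= 2 || n_dev >= 1)
    rec_codes <- c(rec_codes, "DISCUSS_WITH_CLINICIAN")

  structure(list(patient_id = curr$patient_id, side = curr$side,
                 from = prev$timestamp, to = curr$timestamp,
                 deltas = tab, flags = flags,
                 recommendations = rec_codes,
                 thresholds = thresholds),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> patient %s, %s hand, %s -> %s\n",
              x$patient_id, x$side, format(x$from, "%Y-%m-%d"),
              format(x$to, "%Y-%m-%d")))
  if (!length(x$flags)) cat("no flags\n") else
    for (f in x$flags)
      cat(sprintf("  %s: %s %s (%+.1f %s)\n", f$type, f$finger, f$joint,
                  if (!is.null(f$delta_mm)) f$delta_mm else f$delta_deg,
                  if (!is.null(f$delta_mm)) "mm" else "deg"))
  cat("recommendations:", paste(x$recommendations, collapse = ", "), "\n")
  invisible(x)
}

#' Per-metric trend over a series of records
#'
#' Least-squares slope of each metric against time, in units per month
#' (30.44 days).
#'
#' @param records List of `measurement_record`s (same patient and side),
#'   in any order.
#' @return data.frame with `metric`, `slope_per_month`, `n`, `span_days`;
#'   zero rows when fewer than two records are supplied.
#' @export
series_trend <- function(records) {
  empty <- data.frame(metric = character(), slope_per_month = numeric(),
                      n = integer(), span_days = numeric())
  if (length(records) < 2) return(empty)
  ts <- as.numeric(vapply(records, function(r) as.numeric(r$timestamp), 0))
  ord <- order(ts)
  records <- records[ord]; ts <- ts[ord]
  months <- (ts - ts[1]) / (86400 * 30.44)
  mats <- lapply(records, record_metrics)
  metrics <- Reduce(intersect, lapply(mats, names))
  rows <- lapply(metrics, function(m) {
    y <- vapply(mats, function(v) v[[m]], 0)
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NULL)
    fit <- stats::lm.fit(cbind(1, months[ok]), y[ok])
    data.frame(metric = m, slope_per_month = unname(fit$coefficients[2]),
               n = sum(ok), span_days = (max(ts) - min(ts)) / 86400)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Append a record to a JSON-lines store
#'
#' One patient per file; records are append-only and kept chronologically
#' consistent by the reader.
#'
#' @param record A `measurement_record`.
#' @param path JSON-lines file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  x <- record
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  m <- unclass(x$measurements)
  # named vectors must become JSON objects, not bare arrays
  m$fingers <- lapply(m$fingers, function(f) lapply(f, as.list))
  x$measurements <- m
  line <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(as.character(line), con)
  invisible(path)
}

#' Read all records from a JSON-lines store
#'
#' @param path JSON-lines file written by [write_record()].
#' @return List of `measurement_record`s, ordered by timestamp.
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    m <- x$measurements
    m$fingers <- lapply(m$fingers, function(f) {
      for (nm in c("joint_arc_mm", "thickness_mm", "angulation_deg", "deviation_deg"))
        f[[nm]] <- unlist(f[[nm]])
      f$low_confidence <- unlist(f$low_confidence)
      f
    })
    class(m) <- "hand_measurements"
    measurement_record(x$patient_id, as.POSIXct(x$timestamp, tz = "UTC",
                                                format = "%Y-%m-%dT%H:%M:%SZ"),
                       x$side, m, validation = NULL)
  })
  ts <- vapply(recs, function(r) as.numeric(r$timestamp), 0)
  recs[order(ts)]
}
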