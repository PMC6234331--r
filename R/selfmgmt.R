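# Minimal self-management log: daily pain scores with treatment and
# lifestyle tags, range-validated outcome scores, and a flare look-back
# summary ("what was different in the days before a flare?").
#
# Proprietary instruments (PROMIS P-SEMS, PAM) are deliberately not
# implemented; only score containers with their documented ranges are
# provided (HAQ-II in [0, 3], VAS pain in [0, 10]).

#' Create an empty symptom log
#'
#' @return A `symptom_log` with zero entries.
#' @export
symptom_log <- function() {
  structure(list(
    entries = data.frame(date = as.Date(character()), pain = numeric(),
                         note = character()),
    tags = data.frame(date = as.Date(character()), tag = character(),
                      type = character())
  ), class = "symptom_log")
}

#' Add a symptom entry
#'
#' Appends a dated entry with a pain score on the 0–10 visual analog
#' scale, optional note, and treatment/lifestyle tags (e.g. diet,
#' activity, weather).  The log is append-only and kept in chronological
#' order; duplicate dates are allowed and all retained.
#'
#' @param log A `symptom_log`.
#' @param date Entry date (coerced with `as.Date`).
#' @param pain Pain score in [0, 10].
#' @param note Optional free-text note.
#' @param treatments Character vector of treatment tags.
#' @param lifestyle Character vector of lifestyle tags.
#' @return The updated log.
#' @export
add_entry <- function(log, date, pain, note = "", treatments = character(),
                      lifestyle = character()) {
  date <- as.Date(date)
  if (is.na(date)) hm_error("range_error", "invalid date")
  if (!is.numeric(pain) || length(pain) != 1 || is.na(pain) ||
      pain < 0 || pain > 10)
    hm_error("range_error", sprintf("pain score %s outside [0, 10]", format(pain)))
  log$entries <- rbind(log$entries,
                       data.frame(date = date, pain = pain, note = note))
  if (length(treatments))
    log$tags <- rbind(log$tags, data.frame(date = date, tag = treatments,
                                           type = "treatment"))
  if (length(lifestyle))
    log$tags <- rbind(log$tags, data.frame(date = date, tag = lifestyle,
                                           type = "lifestyle"))
  ord <- order(log$entries$date)
  log$entries <- log$entries[ord, , drop = FALSE]
  rownames(log$entries) <- NULL
  log
}

#' Tag frequencies in the window before a flare
#'
#' Counts every treatment/lifestyle tag logged in the `window_days` days
#' strictly before `flare_date` (inclusive of `flare_date - window_days`,
#' exclusive of the flare day itself) — the "did I do anything different
#' before I flared?" look-back.
#'
#' @param log A `symptom_log`.
#' @param flare_date Date of the flare.
#' @param window_days Positive integer window length.
#' @return data.frame with `tag`, `type`, `count`, sorted by count.
#' @export
flare_lookback <- function(log, flare_date, window_days) {
  if (window_days < 1) hm_error("range_error", "window_days must be >= 1")
  flare_date <- as.Date(flare_date)
  empty <- data.frame(tag = character(), type = character(), count = integer())
  if (!nrow(log$tags)) return(empty)
  sel <- log$tags$date >= flare_date - window_days & log$tags$date < flare_date
  if (!any(sel)) return(empty)
  agg <- stats::aggregate(list(count = rep(1L, sum(sel))),
                          by = list(tag = log$tags$tag[sel],
                                    type = log$tags$type[sel]),
                          FUN = sum)
  agg <- agg[order(-agg$count, agg$tag), c("tag", "type", "count")]
  rownames(agg) <- NULL
  agg
}

#' Range-validated outcome score
#'
#' Containers for the two implemented health outcomes: HAQ-II disability
#' (0 = minimum loss of function to 3 = completely disabled) and VAS pain
#' (0 = no pain to 10 = worst pain).
#'
#' @param instrument `"HAQ-II"` or `"VAS"`.
#' @param value Score value within the instrument's range.
#' @param date Assessment date.
#' @return An `outcome_score`.
#' @export
outcome_score <- function(instrument = c("HAQ-II", "VAS"), value, date) {
  instrument <- match.arg(instrument)
  rng <- if (instrument == "HAQ-II") c(0, 3) else c(0, 10)
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < rng[1] || value > rng[2])
    hm_error("range_error",
             sprintf("%s score %s outside [%g, %g]", instrument,
                     format(value), rng[1], rng[2]))
  structure(list(instrument = instrument, value = value, date = as.Date(date)),
            class = "outcome_score")
}

#' @export
print.symptom_log <- function(x, ...) {
  cat(sprintf("<symptom_log> %d entries, %d tags\n", nrow(x$entries), nrow(x$tags)))
  invisible(x)
}
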