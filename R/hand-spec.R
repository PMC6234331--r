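#' Parametric hand specification
#'
#' A `hand_spec` fully determines a flat, spread hand silhouette: a convex
#' palm polygon plus, per finger, a chain of capsule (stadium) segments
#' with linearly interpolated widths.  All lengths are millimetres, all
#' angles degrees.  Angles follow the ulnar-positive convention: positive
#' spread or deviation tilts a finger toward the little-finger side,
#' the clinically relevant direction for rheumatoid deformity.
#'
#' Non-thumb fingers have three segments (proximal, middle, distal),
#' widths at base/PIP/DIP/tip and deviation angles at PIP and DIP.  The
#' thumb has two segments (proximal, distal), widths at base/IP/tip and a
#' single IP deviation.
#'
#' @param handedness `"left"` or `"right"`.
#' @param palm_width_mm,palm_length_mm Palm dimensions.
#' @param fingers Named list (`thumb`, `index`, `middle`, `ring`,
#'   `little`); each element a list with `segment_lengths_mm`,
#'   `widths_mm`, `spread_deg`, `deviation_deg` (named vectors as in
#'   [default_hand_spec()]).
#' @return An object of class `hand_spec`.
#' @seealso [default_hand_spec()], [sample_hand_spec()], [perturb_hand()]
#' @export
hand_spec <- function(handedness, palm_width_mm, palm_length_mm, fingers) {
  spec <- structure(
    list(handedness = handedness,
         palm_width_mm = palm_width_mm,
         palm_length_mm = palm_length_mm,
         fingers = fingers),
    class = "hand_spec")
  validate_hand_spec(spec)
  spec
}

FINGER_NAMES <- c("thumb", "index", "middle", "ring", "little")

#' A realistic default adult right hand
#'
#' Dimensions are round numbers in the range of published adult hand
#' anthropometry; joints are modelled slightly wider than the adjacent
#' phalanx shafts so that they are visible as silhouette bulges.
#'
#' @return A `hand_spec`.
#' @export
default_hand_spec <- function() {
  f <- function(lengths, widths, spread, dev) {
    list(segment_lengths_mm = c(proximal = lengths[1], middle = lengths[2], distal = lengths[3]),
         widths_mm = c(base = widths[1], pip = widths[2], dip = widths[3], tip = widths[4]),
         spread_deg = spread,
         deviation_deg = c(pip = dev[1], dip = dev[2]))
  }
  hand_spec(
    handedness = "right",
    palm_width_mm = 85, palm_length_mm = 95,
    fingers = list(
      thumb = list(
        segment_lengths_mm = c(proximal = 32, distal = 28),
        widths_mm = c(base = 20, ip = 18, tip = 15),
        spread_deg = -46,
        deviation_deg = c(ip = 0)),
      index  = f(c(34, 22, 16), c(17.0, 18.0, 15.5, 13.0), -9, c(0, 0)),
      middle = f(c(38, 25, 18), c(17.5, 18.5, 16.0, 13.5), -1, c(0, 0)),
      ring   = f(c(36, 23, 17), c(16.5, 17.5, 15.0, 13.0),  5, c(0, 0)),
      little = f(c(28, 18, 14), c(14.5, 15.5, 13.5, 11.5), 14, c(0, 0))
    )
  )
}

#' Validate a hand specification
#'
#' Checks the structural invariants: positive lengths and widths, widths
#' at most 40 mm, absolute deviation angles at most 60 degrees, all five
#' fingers present with the right field shapes.  Geometric validity
#' (fingers not touching, hand within the paper margins) is checked by
#' the renderer, which sees the placed geometry.
#'
#' @param spec A `hand_spec`.
#' @return The spec, invisibly; signals an `invalid_hand_spec` error
#'   otherwise.
#' @export
validate_hand_spec <- function(spec) {
  fail <- function(msg) hm_error("invalid_hand_spec", msg)
  if (!inherits(spec, "hand_spec")) fail("not a hand_spec object")
  if (!spec$handedness %in% c("left", "right")) fail("handedness must be 'left' or 'right'")
  if (!is.numeric(spec$palm_width_mm) || spec$palm_width_mm <= 0 ||
      !is.numeric(spec$palm_length_mm) || spec$palm_length_mm <= 0)
    fail("palm dimensions must be positive")
  if (!identical(sort(names(spec$fingers)), sort(FINGER_NAMES)))
    fail("fingers must be exactly thumb, index, middle, ring, little")
  for (fn in FINGER_NAMES) {
    fg <- spec$fingers[[fn]]
    nseg <- if (fn == "thumb") 2L else 3L
    wn <- if (fn == "thumb") c("base", "ip", "tip") else c("base", "pip", "dip", "tip")
    dn <- if (fn == "thumb") "ip" else c("pip", "dip")
    if (length(fg$segment_lengths_mm) != nseg || any(fg$segment_lengths_mm <= 0))
      fail(sprintf("%s: needs %d positive segment lengths", fn, nseg))
    if (!identical(names(fg$widths_mm), wn) || any(fg$widths_mm <= 0))
      fail(sprintf("%s: widths must be positive and named %s", fn, paste(wn, collapse = "/")))
    if (any(fg$widths_mm > 40)) fail(sprintf("%s: widths must be <= 40 mm", fn))
    if (!identical(names(fg$deviation_deg), dn))
      fail(sprintf("%s: deviation angles must be named %s", fn, paste(dn, collapse = "/")))
    if (any(abs(fg$deviation_deg) > 60)) fail(sprintf("%s: |deviation| must be <= 60 degrees", fn))
    if (!is.numeric(fg$spread_deg) || length(fg$spread_deg) != 1)
      fail(sprintf("%s: spread_deg must be a scalar", fn))
  }
  invisible(spec)
}

#' Default sampling ranges for [sample_hand_spec()]
#'
#' The ranges define the population of synthetic hands used throughout
#' validation: overall size within about 8% of the default hand,
#' per-segment length jitter, width jitter of +/- 1.5 mm, spread jitter of
#' +/- 3 degrees, and interphalangeal deviations up to 15 degrees (PIP) /
#' 10 degrees (DIP) in either direction — spanning normal alignment
#' through moderate rheumatoid drift.
#'
#' @return A named list of `c(min, max)` ranges (and a `handedness`
#'   character vector of allowed values).
#' @export
hand_spec_ranges <- function() {
  list(
    size_factor = c(0.92, 1.08),
    length_factor = c(0.95, 1.05),
    width_jitter_mm = c(-1.5, 1.5),
    spread_jitter_deg = c(-3, 3),
    dev_pip_deg = c(-15, 15),
    dev_dip_deg = c(-10, 10),
    dev_thumb_deg = c(-10, 10),
    handedness = c("left", "right")
  )
}

runif1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

#' Sample a random valid hand specification
#'
#' Draws a hand around [default_hand_spec()] within `ranges`, resampling
#' (bounded retries) until the result passes both the structural
#' invariants and the renderer's geometric validity check (fingers not
#' touching, hand within the paper margin).  Reproducible: the same seed
#' always yields the same spec, and the caller's RNG state is untouched.
#'
#' @param seed Integer seed.
#' @param ranges As [hand_spec_ranges()]; degenerate ranges (min = max)
#'   pin a parameter exactly.
#' @param max_tries Resampling bound before giving up.
#' @return A valid `hand_spec`.
#' @export
sample_hand_spec <- function(seed, ranges = hand_spec_ranges(), max_tries = 60L) {
  ranges <- modify_list_rec(hand_spec_ranges(), ranges)
  with_preserved_rng(seed, {
    for (try in seq_len(max_tries)) {
      spec <- draw_hand_spec(ranges)
      ok <- tryCatch({
        build_hand_geometry(spec)
        TRUE
      }, handmetry_error = function(e) FALSE)
      if (ok) return(spec)
    }
    hm_error("invalid_hand_spec",
             sprintf("no valid hand drawn in %d tries; ranges too extreme", max_tries))
  })
}

draw_hand_spec <- function(ranges) {
  base <- default_hand_spec()
  size <- runif1(ranges$size_factor)
  hd <- if (length(ranges$handedness) == 1) ranges$handedness else
    sample(ranges$handedness, 1)
  base$handedness <- hd
  base$palm_width_mm <- base$palm_width_mm * size * runif1(ranges$length_factor)
  base$palm_length_mm <- base$palm_length_mm * size * runif1(ranges$length_factor)
  for (fn in FINGER_NAMES) {
    fg <- base$fingers[[fn]]
    fg$segment_lengths_mm <- fg$segment_lengths_mm * size *
      vapply(seq_along(fg$segment_lengths_mm), function(i) runif1(ranges$length_factor), 0)
    fg$widths_mm <- pmax(fg$widths_mm * size +
      vapply(seq_along(fg$widths_mm), function(i) runif1(ranges$width_jitter_mm), 0), 6)
    fg$spread_deg <- fg$spread_deg + runif1(ranges$spread_jitter_deg)
    if (fn == "thumb") {
      fg$deviation_deg[["ip"]] <- runif1(ranges$dev_thumb_deg)
    } else {
      fg$deviation_deg[["pip"]] <- runif1(ranges$dev_pip_deg)
      fg$deviation_deg[["dip"]] <- runif1(ranges$dev_dip_deg)
    }
    base$fingers[[fn]] <- fg
  }
  validate_hand_spec(base)
  base
}

# Run code with a private RNG stream; the caller's .Random.seed survives.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Perturb selected fields of a hand specification
#'
#' Adds the given deltas to the addressed numeric fields, leaving every
#' other field untouched — the primitive used to build longitudinal test
#' pairs (e.g. a +2 mm swollen PIP).
#'
#' @param hand A `hand_spec`.
#' @param deltas Nested named list mirroring the spec structure; leaves
#'   are named numeric vectors of additive deltas, e.g.
#'   `list(fingers = list(middle = list(widths_mm = c(pip = 2))))`.
#' @return The perturbed, validated `hand_spec`.
#' @examples
#' h <- default_hand_spec()
#' h2 <- perturb_hand(h, list(fingers = list(middle = list(widths_mm = c(pip = 2)))))
#' h2$fingers$middle$widths_mm["pip"] - h$fingers$middle$widths_mm["pip"]
#' @export
perturb_hand <- function(hand, deltas) {
  out <- add_deltas(unclass(hand), deltas)
  class(out) <- "hand_spec"
  validate_hand_spec(out)
  build_hand_geometry(out)  # geometric validity too
  out
}

add_deltas <- function(base, deltas) {
  for (nm in names(deltas)) {
    if (is.null(base[[nm]]))
      hm_error("invalid_hand_spec", sprintf("unknown field '%s' in deltas", nm))
    if (is.list(deltas[[nm]])) {
      base[[nm]] <- add_deltas(base[[nm]], deltas[[nm]])
    } else {
      d <- deltas[[nm]]
      if (is.null(names(d)) && length(d) == 1 && !is.null(names(base[[nm]])) &&
          length(base[[nm]]) > 1)
        hm_error("invalid_hand_spec", "scalar delta for a named vector needs a name")
      if (is.null(names(d))) {
        base[[nm]] <- base[[nm]] + d
      } else {
        if (!all(names(d) %in% names(base[[nm]])))
          hm_error("invalid_hand_spec", sprintf("unknown element(s) in delta for '%s'", nm))
        base[[nm]][names(d)] <- base[[nm]][names(d)] + d
      }
    }
  }
  base
}

#' @export
print.hand_spec <- function(x, ...) {
  cat(sprintf("<hand_spec> %s hand, palm %.1f x %.1f mm\n",
              x$handedness, x$palm_width_mm, x$palm_length_mm))
  for (fn in FINGER_NAMES) {
    fg <- x$fingers[[fn]]
    cat(sprintf("  %-6s len %s mm, widths %s mm, spread %+.1f deg, dev %s deg\n", fn,
                paste(sprintf("%.0f", fg$segment_lengths_mm), collapse = "/"),
                paste(sprintf("%.1f", fg$widths_mm), collapse = "/"),
                fg$spread_deg,
                paste(sprintf("%+.1f", fg$deviation_deg), collapse = "/")))
  }
  invisible(x)
}
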