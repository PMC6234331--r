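# The three measurement families recovered from the silhouette:
# finger/joint thickness (width profile along the centerline), finger
# segment angulation (angles between adjacent segment directions), and
# interphalangeal angular deviation (the same angle, signed toward the
# ulnar side).  Joints are localized as width maxima inside anatomical
# fractional windows of the finger length, the only joint cue a
# silhouette offers.

#' Silhouette width profile along a finger centerline
#'
#' At every 0.5 mm arc step along the centerline, the width is the length
#' of the silhouette chord through the centerline point perpendicular to
#' the local centerline direction; taking the chord that contains the
#' point clips it to the finger's own lobe.
#'
#' @param boundary A `hand_boundary`.
#' @param centerline n x 2 mm matrix (tip first), as from [finger_axes()].
#' @return Data frame with `arc_mm` (distance from the tip) and `width_mm`.
#' @export
width_profile <- function(boundary, centerline) {
  cl <- resample_polyline(centerline, 0.5)
  n <- nrow(cl)
  arc <- polyline_arc(cl)
  i0 <- pmax(seq_len(n) - 1L, 1L); i1 <- pmin(seq_len(n) + 1L, n)
  out_arc <- numeric(0); out_w <- numeric(0)
  for (i in seq_len(n)) {
    tg <- cl[i1[i], ] - cl[i0[i], ]
    nt <- sqrt(sum(tg^2))
    if (nt < 1e-9) next
    nrm <- c(-tg[2], tg[1]) / nt
    ch <- polygon_chord(boundary$xy, cl[i, ], nrm)
    if (is.null(ch)) next
    out_arc <- c(out_arc, arc[i]); out_w <- c(out_w, ch$length)
  }
  data.frame(arc_mm = out_arc, width_mm = out_w)
}

#' Locate finger joints on a width profile
#'
#' DIP is the arc position of the maximum width inside the window
#' 15–35% of the finger length from the tip, PIP inside 40–65% (thumb:
#' a single IP joint inside 25–55%).  A window without an interior local
#' maximum falls back to its midpoint and is flagged low-confidence.
#'
#' @param profile From [width_profile()].
#' @param length_mm Finger length (centerline arc length).
#' @param finger Finger name; `"thumb"` gets the single-IP treatment.
#' @param config A [handmetry_config()].
#' @return List: `arc_mm` (named joint positions from the tip),
#'   `thickness_mm`, `low_confidence` (named logical).
#' @export
locate_joints <- function(profile, length_mm, finger = "index",
                          config = handmetry_config()) {
  jc <- config$joints
  sm_n <- max(1L, round(jc$profile_smooth_mm / 0.5))
  w <- as.vector(smooth_open(cbind(profile$width_mm, 0), sm_n)[, 1])
  arc <- profile$arc_mm
  windows <- if (finger == "thumb") list(ip = jc$thumb_ip_window) else
    list(dip = jc$dip_window, pip = jc$pip_window)
  pos <- numeric(0); thick <- numeric(0); lowc <- logical(0)
  for (jn in names(windows)) {
    rng <- windows[[jn]] * length_mm
    sel <- which(arc >= rng[1] & arc <= rng[2])
    fallback <- TRUE
    if (length(sel) >= 3) {
      interior <- sel[-c(1, length(sel))]
      ismax <- w[interior] > w[interior - 1] & w[interior] >= w[interior + 1]
      if (any(ismax)) {
        cand <- interior[ismax]
        j <- cand[which.max(w[cand])]
        # refine to the bulge centroid: the raw argmax jitters on the
        # flat bulge top, the centroid does not
        nb <- which(abs(arc - arc[j]) <= 2.5)
        wt <- w[nb] - min(w[nb])
        pos[jn] <- if (sum(wt) > 1e-9) sum(arc[nb] * wt) / sum(wt) else arc[j]
        fallback <- FALSE
      }
    }
    if (fallback) {
      mid <- mean(rng)
      j <- which.min(abs(arc - mid))
      pos[jn] <- arc[j]
    }
    # thickness = mean width within +/-1 mm of the joint: insensitive to
    # sub-millimetre localization shifts on the flat bulge top
    nb <- which(abs(arc - pos[jn]) <= 1)
    thick[jn] <- mean(w[nb])
    lowc[jn] <- fallback
  }
  list(arc_mm = pos, thickness_mm = thick, low_confidence = lowc)
}

# Distal-pointing direction of the centerline between two arc positions
# (least-squares line over the points, 20% trimmed at each end).
segment_direction <- function(cl, arc, s0, s1, min_mm = 4) {
  trim <- 0.2 * (s1 - s0)
  sel <- which(arc >= s0 + trim & arc <= s1 - trim)
  if (length(sel) < 3 || (s1 - s0) < min_mm) return(NULL)
  p <- cl[sel, , drop = FALSE]
  mu <- colMeans(p)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  # orient toward the tip (decreasing arc)
  ref <- cl[sel[1], ] - cl[sel[length(sel)], ]
  if (sum(dir * ref) < 0) dir <- -dir
  dir
}

finger_segment_dirs <- function(centerline, joint_arc) {
  cl <- resample_polyline(centerline, 0.5)
  arc <- polyline_arc(cl)
  L <- arc[length(arc)]
  cuts <- c(0, sort(unname(joint_arc)), L)
  dirs <- list()
  for (i in seq_len(length(cuts) - 1))
    dirs[[i]] <- segment_direction(cl, arc, cuts[i], cuts[i + 1])
  dirs   # distal-most first
}

#' Segment angulation at each joint
#'
#' Fits a direction to the centerline of each phalangeal segment and
#' reports the angle between adjacent segment directions, in [0, 180).
#' Segments shorter than 4 mm give an undefined (NA) angle.
#'
#' @param centerline n x 2 matrix (tip first).
#' @param joint_arc Named joint arc positions from [locate_joints()].
#' @return Named numeric vector of angles (degrees), NA where undefined.
#' @export
segment_angulation <- function(centerline, joint_arc) {
  dirs <- finger_segment_dirs(centerline, joint_arc)
  jn <- names(sort(joint_arc))       # distal joint first
  out <- stats::setNames(rep(NA_real_, length(jn)), jn)
  for (i in seq_along(jn)) {
    a <- dirs[[i]]; b <- dirs[[i + 1]]
    if (!is.null(a) && !is.null(b)) out[jn[i]] <- vec_angle_deg(b, a)
  }
  out
}

#' Signed interphalangeal angular deviation
#'
#' The angle between adjacent segment directions, signed positive when
#' the distal segment tilts toward the ulnar (little-finger) side —
#' the direction of the classic rheumatoid drift.
#'
#' @param centerline n x 2 matrix (tip first).
#' @param joint_arc Named joint arcs from [locate_joints()].
#' @param ulnar Unit vector pointing to the ulnar side of the hand.
#' @return Named numeric vector of signed angles (degrees).
#' @export
angular_deviation <- function(centerline, joint_arc, ulnar) {
  dirs <- finger_segment_dirs(centerline, joint_arc)
  jn <- names(sort(joint_arc))
  out <- stats::setNames(rep(NA_real_, length(jn)), jn)
  for (i in seq_along(jn)) {
    d_out <- dirs[[i]]       # distal side of the joint
    d_in <- dirs[[i + 1]]    # proximal side
    if (is.null(d_out) || is.null(d_in)) next
    lat <- ulnar - sum(ulnar * d_in) * d_in
    nl <- sqrt(sum(lat^2))
    if (nl < 1e-9) next
    lat <- lat / nl
    out[jn[i]] <- vec_angle_deg(d_in, d_out) * sign(sum(d_out * lat))
  }
  out
}

#' Measure the hand
#'
#' Assembles all per-finger measurements (length, joint positions and
#' thicknesses, segment angulation, signed angular deviation) plus palm
#' width and hand span from the boundary and landmarks.  Deterministic:
#' the same inputs always give the same output.
#'
#' @param boundary A `hand_boundary`.
#' @param landmarks A `hand_landmarks`.
#' @param cal Optional `calibration_model`; only its centre scale is
#'   recorded.
#' @param config A [handmetry_config()].
#' @return A `hand_measurements` object.
#' @export
measure_hand <- function(boundary, landmarks, cal = NULL,
                         config = handmetry_config()) {
  axes <- finger_axes(boundary, landmarks, config)
  a <- normalize(colMeans(axes$middle$base_chord) - landmarks$wrist_mid)
  w <- landmarks$tips["little", ] - landmarks$tips["thumb", ]
  ulnar <- normalize(w - sum(w * a) * a)
  fingers <- list()
  for (fn in FINGER_NAMES) {
    cl <- axes[[fn]]$centerline
    arc <- polyline_arc(cl)
    L <- arc[length(arc)]
    prof <- width_profile(boundary, cl)
    j <- locate_joints(prof, L, finger = fn, config = config)
    ang <- segment_angulation(cl, j$arc_mm)
    dev <- angular_deviation(cl, j$arc_mm, ulnar)
    fingers[[fn]] <- list(
      length_mm = L,
      joint_arc_mm = j$arc_mm,
      thickness_mm = j$thickness_mm,
      angulation_deg = ang,
      deviation_deg = dev,
      low_confidence = j$low_confidence
    )
  }
  # palm width: silhouette chord perpendicular to the hand axis just below
  # the valleys (before the thumb joins the palm)
  p0 <- colMeans(axes$middle$base_chord)
  q <- p0 - a * 8
  ch <- polygon_chord(boundary$xy, q, c(-a[2], a[1]))
  palm_width <- if (is.null(ch)) NA_real_ else ch$length
  structure(list(
    fingers = fingers,
    palm_width_mm = palm_width,
    span_mm = dist2(landmarks$tips["thumb", ], landmarks$tips["little", ]),
    handedness = landmarks$handedness,
    scale_mm_per_px = if (is.null(cal)) NA_real_ else cal$center_scale_mm_per_px
  ), class = "hand_measurements")
}

#' @export
print.hand_measurements <- function(x, ...) {
  cat(sprintf("<hand_measurements> %s hand, span %.1f mm, palm width %.1f mm\n",
              x$handedness, x$span_mm, x$palm_width_mm))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten measurements to a long data frame
#'
#' One row per (finger, metric): suitable for CSV export and for
#' longitudinal series assembly.
#'
#' @param x A `hand_measurements`.
#' @param ... Unused.
#' @return data.frame with columns `finger`, `metric`, `value`.
#' @export
as.data.frame.hand_measurements <- function(x, ...) {
  rows <- list()
  add <- function(finger, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(finger = finger, metric = metric,
                                            value = as.numeric(value))
  for (fn in names(x$fingers)) {
    f <- x$fingers[[fn]]
    add(fn, "length_mm", f$length_mm)
    for (jn in names(f$joint_arc_mm)) {
      add(fn, paste0("joint_arc_", jn, "_mm"), f$joint_arc_mm[jn])
      add(fn, paste0("thickness_", jn, "_mm"), f$thickness_mm[jn])
      add(fn, paste0("angulation_", jn, "_deg"), f$angulation_deg[jn])
      add(fn, paste0("deviation_", jn, "_deg"), f$deviation_deg[jn])
    }
  }
  add("hand", "palm_width_mm", x$palm_width_mm)
  add("hand", "span_mm", x$span_mm)
  do.call(rbind, rows)
}
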