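# Silhouette landmarking: fingertips, interdigital valleys, handedness,
# and per-finger centerlines traced as chains of cross-section midpoints.

#' Detect fingertips and interdigital valleys
#'
#' Fingertips are the five strongest convex boundary points that are also
#' local maxima of distance from the wrist midpoint (minimum peak
#' separation 15 mm of boundary arc); each valley is the deepest boundary
#' point between an adjacent tip pair.  Tips are then refined against the
#' finger's own base (the adjacent-valley midpoint) so the reported tip
#' is the apex of the finger, not merely the point farthest from the
#' wrist.  Handedness follows from the thumb side: a hand resting
#' palm-down with fingers toward the paper top has its thumb on the left
#' for a right hand.
#'
#' @param boundary A `hand_boundary` from [extract_boundary()].
#' @param config A [handmetry_config()].
#' @return A `hand_landmarks`: `tips` (5 x 2 mm, thumb..little), `valleys`
#'   (4 x 2), `lateral` (wrist-chord endpoints, radial/ulnar), `wrist_mid`,
#'   `handedness`, and the boundary indices of each landmark.
#' @export
detect_fingertips_valleys <- function(boundary, config = handmetry_config()) {
  lc <- config$landmarks
  if (is.null(boundary$wrist_chord))
    hm_error("no_hand_found", "boundary has no wrist chord; silhouette does not reach the bottom edge")
  xy <- boundary$xy
  n <- nrow(xy)
  step <- boundary$perimeter_mm / n
  wrist_mid <- colMeans(boundary$wrist_chord)
  d <- sqrt((xy[, 1] - wrist_mid[1])^2 + (xy[, 2] - wrist_mid[2])^2)

  k <- max(2L, round(lc$curvature_window_mm / step))
  im <- ((seq_len(n) - 1 - k) %% n) + 1
  ip <- ((seq_len(n) - 1 + k) %% n) + 1
  crossz <- (xy[, 1] - xy[im, 1]) * (xy[ip, 2] - xy[, 2]) -
            (xy[, 2] - xy[im, 2]) * (xy[ip, 1] - xy[, 1])
  convex <- crossz > 0

  win <- max(2L, round(lc$min_tip_separation_mm / step))
  cand <- which(convex & d > vapply(seq_len(n), function(i) {
    idx <- ((i - 1 + c(-win:-1, 1:win)) %% n) + 1
    max(d[idx])
  }, 0))
  if (length(cand) < 5)
    hm_error("fingers_not_spread",
             sprintf("only %d fingertip candidates found", length(cand)))
  cand <- cand[order(d[cand], decreasing = TRUE)]
  tips_idx <- sort(cand[1:5])

  valley_idx <- integer(4)
  for (g in 1:4) {
    seg <- (tips_idx[g] + 1):(tips_idx[g + 1] - 1)
    valley_idx[g] <- seg[which.min(d[seg])]
    depth <- min(d[tips_idx[g]], d[tips_idx[g + 1]]) - d[valley_idx[g]]
    if (depth < lc$min_valley_depth_mm)
      hm_error("fingers_not_spread",
               sprintf("interdigital valley depth %.1f mm < %g mm", depth,
                       lc$min_valley_depth_mm))
  }

  # thumb is the isolated end digit: larger mean distance to the others
  tp <- xy[tips_idx, , drop = FALSE]
  md <- function(i) mean(sqrt((tp[, 1] - tp[i, 1])^2 + (tp[, 2] - tp[i, 2])^2))
  thumb_first <- md(1) > md(5)
  if (!thumb_first) {
    tips_idx <- rev(tips_idx)
    valley_idx <- rev(valley_idx)
  }
  tips <- xy[tips_idx, , drop = FALSE]
  rownames(tips) <- FINGER_NAMES
  valleys <- xy[valley_idx, , drop = FALSE]
  rownames(valleys) <- c("thumb_index", "index_middle", "middle_ring", "ring_little")

  handedness <- if (tips["thumb", 1] < wrist_mid[1]) "right" else "left"
  ends <- boundary$wrist_chord
  thumb_side <- which.min(abs(ends[, 1] - tips["thumb", 1]))
  lateral <- ends[c(thumb_side, 3 - thumb_side), , drop = FALSE]
  rownames(lateral) <- c("radial", "ulnar")

  # refine each tip to the finger apex: estimate the local finger axis
  # with a short midpoint trace, then take the extreme boundary point in
  # the distal direction within a small window around the peak
  ref_win <- max(1L, round(lc$tip_refine_arc_mm / step))
  for (f in 1:5) {
    base_ref <- switch(f,
      (valleys["thumb_index", ] + lateral["radial", ]) / 2,   # thumb
      (valleys["thumb_index", ] + valleys["index_middle", ]) / 2,
      (valleys["index_middle", ] + valleys["middle_ring", ]) / 2,
      (valleys["middle_ring", ] + valleys["ring_little", ]) / 2,
      (valleys["ring_little", ] + lateral["ulnar", ]) / 2)    # little
    ax <- local_axis(xy, tips[f, ], base_ref)                 # points proximal
    i0 <- tips_idx[f]
    idx <- ((i0 - 1 + (-ref_win:ref_win)) %% n) + 1
    proj <- xy[idx, 1] * ax[1] + xy[idx, 2] * ax[2]
    tips_idx[f] <- idx[which.min(proj)]
    tips[f, ] <- xy[tips_idx[f], ]
  }

  structure(list(tips = tips, valleys = valleys, lateral = lateral,
                 wrist_mid = wrist_mid, handedness = handedness,
                 tip_idx = tips_idx, valley_idx = valley_idx),
            class = "hand_landmarks")
}

#' @export
print.hand_landmarks <- function(x, ...) {
  cat(sprintf("<hand_landmarks> %s hand; 5 tips, 4 valleys\n", x$handedness))
  print(round(x$tips, 1))
  invisible(x)
}

# Short chord-midpoint trace from the tip toward a rough base reference;
# returns the proximal-pointing local finger axis.
local_axis <- function(poly, tip, toward, steps = 5L, step = 2.5) {
  dir <- normalize(toward - tip)
  p <- tip + 2.5 * dir
  mids <- matrix(NA_real_, 0, 2)
  prev <- tip
  for (s in seq_len(steps)) {
    ch <- polygon_chord(poly, p, c(-dir[2], dir[1]))
    if (is.null(ch)) break
    mids <- rbind(mids, ch$mid)
    dir <- normalize(0.5 * dir + 0.5 * normalize(ch$mid - prev))
    prev <- ch$mid
    p <- ch$mid + step * dir
  }
  if (nrow(mids) >= 2) normalize(mids[nrow(mids), ] - mids[1, ]) else dir
}

#' Trace per-finger centerlines
#'
#' For each finger, marches from the refined tip toward the finger base,
#' taking at every step the silhouette chord perpendicular to the running
#' direction and advancing through its midpoint; the chain of midpoints,
#' smoothed over 2 mm, is the centerline.  It ends on the finger's base
#' chord (the valley-to-valley line, or valley-to-outer-base for the
#' thumb and little finger).
#'
#' @param boundary A `hand_boundary`.
#' @param lm A `hand_landmarks`.
#' @param config A [handmetry_config()].
#' @return Named list (thumb..little) of list(centerline = n x 2 mm
#'   matrix from tip to base, base_chord = 2 x 2).
#' @export
finger_axes <- function(boundary, lm, config = handmetry_config()) {
  xy <- boundary$xy
  wrist_mid <- lm$wrist_mid
  v <- lm$valleys
  out <- list()
  # distal-pointing hand axis used as the base-plane normal for the
  # index and little fingers (their outer side has no second valley)
  a_h <- normalize(colMeans(v[c("index_middle", "middle_ring"), ]) - wrist_mid)
  for (f in seq_along(FINGER_NAMES)) {
    fn <- FINGER_NAMES[f]
    # interior fingers end on the valley-to-valley chord; index and
    # little end on the hand-axis plane through their single adjacent
    # valley; the thumb ends on the plane through its webbing valley
    # perpendicular to the thumb's own running direction
    spec <- switch(fn,
      thumb = list(stop = "level", anchor = v["thumb_index", ], normal = NULL,
                   toward = (v["thumb_index", ] + lm$lateral["radial", ]) / 2),
      index = list(stop = "level", anchor = v["index_middle", ], normal = a_h,
                   toward = (v["thumb_index", ] + v["index_middle", ]) / 2),
      middle = list(stop = "chord", a = v["index_middle", ], b = v["middle_ring", ]),
      ring = list(stop = "chord", a = v["middle_ring", ], b = v["ring_little", ]),
      little = list(stop = "level", anchor = v["ring_little", ], normal = a_h,
                    toward = (v["ring_little", ] + lm$lateral["ulnar", ]) / 2))
    cl <- trace_centerline(xy, lm$tips[fn, ], spec)
    base_chord <- if (spec$stop == "chord") rbind(spec$a, spec$b) else
      rbind(spec$anchor, 2 * cl[nrow(cl), ] - spec$anchor)
    out[[fn]] <- list(centerline = cl, base_chord = base_chord)
  }
  out
}

trace_centerline <- function(poly, tip, spec, step = 1) {
  if (spec$stop == "chord") {
    base_mid <- (spec$a + spec$b) / 2
    e_hat <- normalize(spec$b - spec$a)
    perp <- c(-e_hat[2], e_hat[1])
    side0 <- sign(sum(perp * (tip - spec$a)))
  } else base_mid <- spec$toward
  dir <- normalize(base_mid - tip)
  pts <- matrix(tip, 1)
  widths <- numeric(0)
  prev <- tip
  p <- tip + 2 * dir
  for (iter in 1:300) {
    nrm <- c(-dir[2], dir[1])
    ch <- polygon_chord(poly, p, nrm)
    if (is.null(ch)) break
    m <- ch$mid
    # signed distances to the base line/plane, positive past the base
    if (spec$stop == "chord") {
      nvec <- perp * -side0
      s_m <- sum(nvec * (m - spec$a))
      s_prev <- sum(nvec * (prev - spec$a))
    } else {
      nvec <- if (is.null(spec$normal)) dir else -spec$normal
      s_m <- sum(nvec * (m - spec$anchor))
      s_prev <- sum(nvec * (prev - spec$anchor))
    }
    med <- if (length(widths) >= 10) stats::median(widths[1:10]) else Inf
    spilled <- ch$length > 2.2 * med     # chord escaped into the palm
    if (s_m > -0.6 || (spilled && s_prev > -4)) {
      # finish on the base plane by extrapolating the last good midpoint
      den <- sum(dir * nvec)
      if (abs(den) > 1e-6) {
        t <- min(max(-s_prev / den, 0), 4)
        pts <- rbind(pts, prev + t * dir)
      }
      break
    }
    if (spilled) break
    widths <- c(widths, ch$length)
    pts <- rbind(pts, m)
    dir <- normalize(0.7 * dir + 0.3 * normalize(m - prev))
    prev <- m
    p <- m + step * dir
  }
  if (nrow(pts) < 4)
    hm_error("degenerate_geometry", "centerline trace collapsed")
  sm <- smooth_open(pts[-1, , drop = FALSE], 5)
  sm[nrow(sm), ] <- pts[nrow(pts), ]   # keep the base-plane endpoint exact
  resample_polyline(rbind(pts[1, ], sm), 0.5)
}
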