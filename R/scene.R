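# Synthetic hand/paper scene renderer with exact ground truth.
#
# The hand model is a convex palm polygon plus per-finger chains of
# stadium (capsule) segments whose radius is piecewise-linear along the
# chain: full width at the joints, a slightly narrower waist mid-phalanx,
# so joints appear as the silhouette bulges the measurement pipeline
# must find.  The hand is placed in the canonical paper frame (portrait,
# origin top-left, fingers toward y = 0, wrist crossing the bottom edge)
# and the whole paper plane is warped into the image by a projective pose.

JOINT_WAIST <- 0.92   # mid-phalanx width relative to the narrower adjacent joint
GT_RASTER_RES <- 5    # px/mm for the ground-truth silhouette raster

#' Scene (capture geometry) specification
#'
#' Describes how the paper plane is photographed: resolution, in-plane
#' rotation, two perspective tilt parameters, surface intensities, sensor
#' noise and blur, and the random seed that fully determines the render.
#'
#' @param px_per_mm Nominal resolution on the paper plane (pixels per mm).
#' @param rotation_deg In-plane rotation of the paper in the image.
#' @param tilt Length-2 numeric, perspective row of the pose homography
#'   (units 1/mm; magnitudes up to ~3e-4 give mild, realistic tilt).
#' @param translation_px Optional fixed translation; `NULL` (default)
#'   auto-centres the paper with `margin_mm` of background on all sides.
#' @param image_size_px Optional fixed `c(nx, ny)`; `NULL` sizes the
#'   canvas automatically.
#' @param paper_intensity,background_intensity,hand_intensity Surface
#'   intensities in [0, 1]; the background must be darker than the paper.
#' @param noise_sd Additive Gaussian intensity noise (applied before blur).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables).
#' @param seed Integer; fully determines the render.
#' @param margin_mm Background margin around the paper for auto layout.
#' @param hand_offset_mm Translation applied to the hand on the paper,
#'   used to construct capture-rule violations.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(px_per_mm = 5, rotation_deg = 0, tilt = c(0, 0),
                       translation_px = NULL, image_size_px = NULL,
                       paper_intensity = 0.85, background_intensity = 0.30,
                       hand_intensity = 0.45, noise_sd = 0, blur_sigma_px = 1,
                       seed = 1L, margin_mm = 8, hand_offset_mm = c(0, 0)) {
  if (background_intensity >= paper_intensity)
    hm_error("invalid_scene", "background must be strictly darker than the paper")
  if (px_per_mm <= 0) hm_error("invalid_scene", "px_per_mm must be positive")
  structure(list(px_per_mm = px_per_mm, rotation_deg = rotation_deg,
                 tilt = tilt, translation_px = translation_px,
                 image_size_px = image_size_px,
                 paper_intensity = paper_intensity,
                 background_intensity = background_intensity,
                 hand_intensity = hand_intensity, noise_sd = noise_sd,
                 blur_sigma_px = blur_sigma_px, seed = as.integer(seed),
                 margin_mm = margin_mm, hand_offset_mm = hand_offset_mm),
            class = "scene_spec")
}

# Rotate v toward the ulnar direction u by ang degrees (ulnar-positive).
rotate_ulnar <- function(v, ang, u) {
  lat <- u - sum(u * v) * v
  nl <- sqrt(sum(lat^2))
  if (nl < 1e-9) hm_error("degenerate_geometry", "finger direction parallel to ulnar axis")
  lat <- lat / nl
  s <- sign(cross2(v, lat))
  as.vector(rot2(ang * s) %*% v)
}

# Place the hand in the canonical paper frame and derive all ground-truth
# geometry.  Errors if fingers touch or the hand exceeds the paper margin.
build_hand_geometry <- function(spec, margin_mm = 5, check = TRUE) {
  validate_hand_spec(spec)
  paper <- PAPER_MM
  a <- c(0, -1)                                   # distal (fingers) direction
  u <- if (spec$handedness == "right") c(1, 0) else c(-1, 0)  # ulnar side
  cx <- paper[1] / 2
  W <- spec$palm_width_mm; Lp <- spec$palm_length_mm

  # provisional knuckle line at y = 0, shifted after measuring finger reach
  mk_fingers <- function(y_k) {
    # four finger bases across the palm top, radial to ulnar
    off <- c(-0.36, -0.12, 0.12, 0.36) * W
    bases <- lapply(off, function(o) c(cx, y_k) + o * u)
    names(bases) <- c("index", "middle", "ring", "little")
    bases$thumb <- c(cx, y_k + 0.30 * Lp) - (W / 2) * u
    out <- list()
    for (fn in FINGER_NAMES) {
      fg <- spec$fingers[[fn]]
      lens <- unname(fg$segment_lengths_mm)
      dirs <- list(rotate_ulnar(a, fg$spread_deg, u))
      for (dv in fg$deviation_deg)
        dirs[[length(dirs) + 1]] <- rotate_ulnar(dirs[[length(dirs)]], dv, u)
      pts <- matrix(0, length(lens) + 1, 2)
      pts[1, ] <- bases[[fn]]
      for (i in seq_along(lens)) pts[i + 1, ] <- pts[i, ] + lens[i] * dirs[[i]]
      w <- unname(fg$widths_mm)          # base, [pip,] dip|ip, tip
      r <- w / 2
      sj <- c(0, cumsum(lens))           # arc from base at each joint
      # knots: joints plus mid-phalanx waists
      ks <- c(); kr <- c()
      for (i in seq_along(lens)) {
        ks <- c(ks, sj[i], (sj[i] + sj[i + 1]) / 2)
        kr <- c(kr, r[i], JOINT_WAIST * min(r[i], r[i + 1]))
      }
      ks <- c(ks, sj[length(sj)]); kr <- c(kr, r[length(r)])
      dirmat <- do.call(rbind, dirs)
      apex <- pts[nrow(pts), ] + r[length(r)] * dirs[[length(dirs)]]
      L <- sum(lens)
      out[[fn]] <- list(chain = pts, dirs = dirmat, lengths = lens,
                        knot_s = ks, knot_r = kr, apex = apex,
                        total_arc = L, tip_radius = r[length(r)])
    }
    out
  }

  fingers0 <- mk_fingers(0)
  reach <- min(vapply(fingers0, function(f) f$apex[2] - f$tip_radius, 0))
  y_k <- margin_mm + 2 - reach                   # highest silhouette point at margin+2
  fingers <- mk_fingers(y_k)
  y_w <- y_k + Lp

  palm <- rbind(c(cx - W / 2, y_k), c(cx + W / 2, y_k),
                c(cx + 0.36 * W, y_w), c(cx - 0.36 * W, y_w))
  wrist <- rbind(c(cx - 0.34 * W, y_w - 1), c(cx + 0.34 * W, y_w - 1),
                 c(cx + 0.34 * W, paper[2] + 15), c(cx - 0.34 * W, paper[2] + 15))

  geom <- structure(list(
    spec = spec, palm = palm, wrist = wrist, fingers = fingers,
    knuckle_y = y_k, wrist_y = y_w, axis = a, ulnar = u,
    centre_x = cx, margin_mm = margin_mm,
    gt = hand_gt_measurements(spec, fingers)
  ), class = "hand_geometry")

  if (check) {
    check_hand_geometry(geom, margin_mm)
  }
  geom
}

hand_gt_measurements <- function(spec, fingers) {
  out <- list()
  for (fn in FINGER_NAMES) {
    fg <- spec$fingers[[fn]]
    f <- fingers[[fn]]
    lens <- f$lengths
    rt <- f$tip_radius
    if (fn == "thumb") {
      joint_arc <- c(ip = rt + lens[2])
      thick <- c(ip = unname(fg$widths_mm["ip"]))
      ang <- c(ip = abs(unname(fg$deviation_deg["ip"])))
      dev <- c(ip = unname(fg$deviation_deg["ip"]))
    } else {
      joint_arc <- c(dip = rt + lens[3], pip = rt + lens[3] + lens[2])
      thick <- c(dip = unname(fg$widths_mm["dip"]), pip = unname(fg$widths_mm["pip"]))
      ang <- c(dip = abs(unname(fg$deviation_deg["dip"])),
               pip = abs(unname(fg$deviation_deg["pip"])))
      dev <- c(dip = unname(fg$deviation_deg["dip"]),
               pip = unname(fg$deviation_deg["pip"]))
    }
    out[[fn]] <- list(length_mm = rt + sum(lens), joint_arc_mm = joint_arc,
                      thickness_mm = thick, angulation_deg = ang,
                      deviation_deg = dev)
  }
  out
}

check_hand_geometry <- function(geom, margin_mm) {
  paper <- PAPER_MM
  # margin: sample each finger chain densely, include radii; palm corners
  pts <- geom$palm
  rr <- rep(0, nrow(pts))
  for (f in geom$fingers) {
    s <- chain_samples(f, step = 1)
    pts <- rbind(pts, s$pts)
    rr <- c(rr, s$r)
  }
  xmin <- min(pts[, 1] - rr); xmax <- max(pts[, 1] + rr)
  ymin <- min(pts[, 2] - rr)
  if (xmin < margin_mm || xmax > paper[1] - margin_mm || ymin < margin_mm)
    hm_error("hand_outside_margin", sprintf(
      "hand exceeds the %g mm paper margin (x: %.1f..%.1f, y top: %.1f)",
      margin_mm, xmin, xmax, ymin))
  # adjacent fingers must not touch
  ord <- FINGER_NAMES
  for (i in 1:4) {
    A <- chain_samples(geom$fingers[[ord[i]]], step = 1)
    B <- chain_samples(geom$fingers[[ord[i + 1]]], step = 1)
    d2 <- outer(A$pts[, 1], B$pts[, 1], "-")^2 + outer(A$pts[, 2], B$pts[, 2], "-")^2
    gap <- sqrt(d2) - outer(A$r, B$r, "+")
    if (min(gap) < 2)
      hm_error("fingers_touching", sprintf(
        "fingers %s and %s are not spread (gap %.2f mm)", ord[i], ord[i + 1], min(gap)))
  }
  invisible(geom)
}

# Sample points and local radii along a finger chain (arc step in mm).
chain_samples <- function(f, step = 1) {
  s <- seq(0, f$total_arc, by = step)
  if (s[length(s)] < f$total_arc) s <- c(s, f$total_arc)
  pts <- chain_point(f, s)
  r <- stats::approx(f$knot_s, f$knot_r, xout = s, rule = 2)$y
  list(pts = pts, r = r, s = s)
}

# Point on the chain at arc distance s from the base (vectorized over s).
chain_point <- function(f, s) {
  sj <- c(0, cumsum(f$lengths))
  seg <- pmin(findInterval(s, sj, rightmost.closed = TRUE), length(f$lengths))
  t <- s - sj[seg]
  f$chain[seg, , drop = FALSE] + f$dirs[seg, , drop = FALSE] * t
}

# Hand membership test for n x 2 mm points (union of palm, wrist and
# tapered-capsule finger chains), with an optional hand translation.
# Bounding-box prefilters keep the vector operations on small subsets.
hand_membership <- function(geom, pts, offset = c(0, 0)) {
  pts <- as_points(pts)
  qx <- pts[, 1] - offset[1]; qy <- pts[, 2] - offset[2]
  inside <- logical(length(qx))
  for (poly in list(geom$palm, geom$wrist)) {
    cand <- which(qx >= min(poly[, 1]) & qx <= max(poly[, 1]) &
                  qy >= min(poly[, 2]) & qy <= max(poly[, 2]))
    if (length(cand))
      inside[cand] <- inside[cand] | points_in_polygon(cbind(qx[cand], qy[cand]), poly)
  }
  for (f in geom$fingers) {
    nk <- length(f$knot_s)
    kp <- chain_point(f, f$knot_s)
    rmaxf <- max(f$knot_r)
    sub <- which(!inside &
                 qx >= min(kp[, 1]) - rmaxf & qx <= max(kp[, 1]) + rmaxf &
                 qy >= min(kp[, 2]) - rmaxf & qy <= max(kp[, 2]) + rmaxf)
    if (!length(sub)) next
    sx <- qx[sub]; sy <- qy[sub]
    hit <- logical(length(sub))
    for (k in seq_len(nk - 1)) {
      ra <- f$knot_r[k]; rb <- f$knot_r[k + 1]
      aa <- kp[k, ]; bb <- kp[k + 1, ]
      rmax <- max(ra, rb)
      cand <- which(!hit &
                    sx >= min(aa[1], bb[1]) - rmax & sx <= max(aa[1], bb[1]) + rmax &
                    sy >= min(aa[2], bb[2]) - rmax & sy <= max(aa[2], bb[2]) + rmax)
      if (!length(cand)) next
      ex <- bb[1] - aa[1]; ey <- bb[2] - aa[2]
      len2 <- ex^2 + ey^2
      t <- ((sx[cand] - aa[1]) * ex + (sy[cand] - aa[2]) * ey) / len2
      t <- pmin(pmax(t, 0), 1)
      dx <- sx[cand] - (aa[1] + t * ex); dy <- sy[cand] - (aa[2] + t * ey)
      r <- ra + t * (rb - ra)
      hit[cand[dx^2 + dy^2 <= r^2]] <- TRUE
    }
    inside[sub[hit]] <- TRUE
  }
  inside
}

#' Rasterize the true hand silhouette on the paper plane
#'
#' @param hand A `hand_spec` or prebuilt hand geometry.
#' @param res Pixels per mm.
#' @param offset Hand translation on the paper (mm).
#' @return Logical `[x, y]` matrix covering the paper rectangle.
#' @export
hand_silhouette_mask <- function(hand, res = GT_RASTER_RES, offset = c(0, 0)) {
  geom <- if (inherits(hand, "hand_geometry")) hand else build_hand_geometry(hand, check = FALSE)
  nx <- round(PAPER_MM[1] * res); ny <- round(PAPER_MM[2] * res)
  bb <- hand_bbox(geom, offset)
  i0 <- max(1L, floor(bb[1] * res)); i1 <- min(nx, ceiling(bb[2] * res))
  j0 <- max(1L, floor(bb[3] * res)); j1 <- min(ny, ceiling(bb[4] * res))
  m <- matrix(FALSE, nx, ny)
  if (i0 > i1 || j0 > j1) return(m)
  xs <- ((i0:i1) - 0.5) / res
  ys <- ((j0:j1) - 0.5) / res
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  m[i0:i1, j0:j1] <- hand_membership(geom, pts, offset = offset)
  m
}

# Pose homography (canonical paper mm -> image px) plus auto layout.
scene_pose <- function(scene) {
  s <- scene$px_per_mm
  P <- diag(3); P[3, 1] <- scene$tilt[1]; P[3, 2] <- scene$tilt[2]
  A <- diag(3)
  A[1:2, 1:2] <- rot2(scene$rotation_deg) * s
  H0 <- A %*% P
  corners_mm <- rbind(c(0, 0), c(PAPER_MM[1], 0), PAPER_MM, c(0, PAPER_MM[2]))
  c0 <- apply_homography(H0, corners_mm)
  if (is.null(scene$translation_px)) {
    m <- scene$margin_mm * s
    tr <- c(m, m) - c(min(c0[, 1]), min(c0[, 2]))
  } else tr <- scene$translation_px
  H <- H0; H[1, ] <- H[1, ] + tr[1] * H0[3, ]; H[2, ] <- H[2, ] + tr[2] * H0[3, ]
  cpx <- apply_homography(H, corners_mm)
  if (is.null(scene$image_size_px)) {
    m <- scene$margin_mm * s
    size <- c(ceiling(max(cpx[, 1]) + m), ceiling(max(cpx[, 2]) + m))
  } else size <- scene$image_size_px
  list(H = H, corners_px = cpx, image_size = size)
}

#' Render a synthetic hand-on-paper scene
#'
#' Rasterizes the hand silhouette on the paper plane, warps it by the
#' scene pose, and applies additive Gaussian noise followed by Gaussian
#' blur.  Fully deterministic for a fixed seed.  Returns the image
#' together with exact ground truth: paper corners, fingertip/valley
#' landmarks (mm and px), the true calibration, and the per-finger
#' measurement values implied by the spec.
#'
#' @param hand A `hand_spec`.
#' @param scene A `scene_spec`.
#' @param validate If `TRUE` (default) reject hands that violate the
#'   5 mm paper margin or whose fingers touch; `FALSE` renders the scene
#'   anyway (used to construct capture-rule violations).
#' @param gt_landmarks If `TRUE`, derive valley/wrist ground truth from a
#'   clean high-resolution silhouette raster (slower); corners, tips and
#'   calibration are always exact.
#' @return List with elements `image` (numeric `[x, y]` matrix in [0, 1])
#'   and `ground_truth`.
#' @export
render_scene <- function(hand, scene, validate = TRUE, gt_landmarks = TRUE) {
  geom <- build_hand_geometry(hand, check = validate)
  if (validate && any(scene$hand_offset_mm != 0)) {
    bb <- hand_bbox(geom, scene$hand_offset_mm)
    if (bb[1] < geom$margin_mm - 1 || bb[2] > PAPER_MM[1] - geom$margin_mm + 1 ||
        bb[3] < geom$margin_mm - 1)
      hm_error("hand_outside_margin", "offset hand exceeds the paper margin")
  }
  pose <- scene_pose(scene)
  nx <- pose$image_size[1]; ny <- pose$image_size[2]
  Hinv <- solve(pose$H)

  xs <- (seq_len(nx)) - 0.5; ys <- (seq_len(ny)) - 0.5
  px <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  mm <- apply_homography(Hinv, px)
  on_paper <- mm[, 1] >= 0 & mm[, 1] <= PAPER_MM[1] &
              mm[, 2] >= 0 & mm[, 2] <= PAPER_MM[2]
  img <- rep(scene$background_intensity, nrow(px))
  img[on_paper] <- scene$paper_intensity
  # antialias the paper border: fractional pixel coverage from the signed
  # distance to the quad (binary sampling would quantize edges that fall
  # mid-pixel to the pixel grid)
  dq <- quad_signed_distance(pose$corners_px, px)
  band <- abs(dq) < 1
  cov <- pmin(pmax(0.5 + dq[band], 0), 1)
  img[band] <- scene$background_intensity +
    cov * (scene$paper_intensity - scene$background_intensity)
  # the hand occludes paper and, where it crosses the wrist edge, background
  bb <- hand_bbox(geom, scene$hand_offset_mm)
  cand <- which(mm[, 1] >= bb[1] & mm[, 1] <= bb[2] &
                mm[, 2] >= bb[3] & mm[, 2] <= bb[4])
  if (length(cand)) {
    member <- hand_membership(geom, mm[cand, , drop = FALSE],
                              offset = scene$hand_offset_mm)
    img[cand[member]] <- scene$hand_intensity
  }
  img <- matrix(img, nx, ny)
  if (scene$noise_sd > 0) {
    img <- with_preserved_rng(scene$seed, {
      img + matrix(stats::rnorm(nx * ny, 0, scene$noise_sd), nx, ny)
    })
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  if (scene$blur_sigma_px > 0)
    img <- gaussian_blur_sep(img, scene$blur_sigma_px)

  gt <- scene_ground_truth(geom, scene, pose, gt_landmarks)
  structure(list(image = img, ground_truth = gt), class = "hand_scene")
}

# Signed distance (px) from points to a convex quad boundary, positive
# inside.
quad_signed_distance <- function(corners, pts) {
  d <- rep(Inf, nrow(pts))
  ctr <- colMeans(corners)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    e <- (b - a) / sqrt(sum((b - a)^2))
    s <- (pts[, 1] - a[1]) * -e[2] + (pts[, 2] - a[2]) * e[1]
    if ((ctr[1] - a[1]) * -e[2] + (ctr[2] - a[2]) * e[1] < 0) s <- -s
    d <- pmin(d, s)
  }
  d
}

hand_bbox <- function(geom, offset = c(0, 0)) {
  pts <- geom$palm
  rr <- rep(0, nrow(pts))
  for (f in geom$fingers) {
    pts <- rbind(pts, f$chain, matrix(f$apex, 1))
    rr <- c(rr, rep(max(f$knot_r), nrow(f$chain) + 1))
  }
  pts <- rbind(pts, geom$wrist)
  rr <- c(rr, rep(0, 4))
  c(min(pts[, 1] - rr) + offset[1] - 1, max(pts[, 1] + rr) + offset[1] + 1,
    min(pts[, 2] - rr) + offset[2] - 1, max(pts[, 2] + rr) + offset[2] + 1)
}

scene_ground_truth <- function(geom, scene, pose, gt_landmarks) {
  off <- scene$hand_offset_mm
  tips_mm <- do.call(rbind, lapply(geom$fingers[FINGER_NAMES], function(f) f$apex + off))
  rownames(tips_mm) <- FINGER_NAMES
  H_px2mm <- solve(pose$H); H_px2mm <- H_px2mm / H_px2mm[3, 3]
  cal_true <- new_calibration(H_px2mm, pose$H)
  gt <- list(
    corners_px = pose$corners_px,
    corners_mm = rbind(c(0, 0), c(PAPER_MM[1], 0), PAPER_MM, c(0, PAPER_MM[2])),
    tips_mm = tips_mm,
    tips_px = apply_homography(pose$H, tips_mm),
    calibration = cal_true,
    hand = geom$spec,
    measurements = geom$gt,
    hand_offset_mm = off,
    pose = pose$H
  )
  if (gt_landmarks) {
    lm <- gt_valleys(geom, off)
    gt$valleys_mm <- lm$valleys
    gt$valleys_px <- apply_homography(pose$H, lm$valleys)
    gt$wrist_mid_mm <- lm$wrist_mid
  }
  gt
}

# Valleys and wrist midpoint from a clean high-res silhouette raster:
# between each pair of adjacent fingertips along the outer contour, the
# valley is the deepest point (closest to the wrist midpoint).
gt_valleys <- function(geom, offset = c(0, 0)) {
  res <- GT_RASTER_RES
  mask <- hand_silhouette_mask(geom, res = res, offset = offset)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  k <- which.max(vapply(oc, nrow, 0L))
  xy <- (oc[[k]] + 0.5) / res
  bottom <- xy[, 2] > PAPER_MM[2] - 1.2 / res - 0.6
  if (!any(bottom)) hm_error("degenerate_geometry", "hand does not reach the wrist edge")
  wrist_mid <- c((min(xy[bottom, 1]) + max(xy[bottom, 1])) / 2, PAPER_MM[2])
  # start the traversal on the wrist edge so fingertip gaps never wrap
  shift <- which(bottom)[1]
  if (shift > 1) xy <- xy[c(shift:nrow(xy), 1:(shift - 1)), , drop = FALSE]
  tips <- do.call(rbind, lapply(geom$fingers[FINGER_NAMES], function(f) f$apex + offset))
  tip_idx <- vapply(seq_len(nrow(tips)), function(i)
    which.min((xy[, 1] - tips[i, 1])^2 + (xy[, 2] - tips[i, 2])^2), 0L)
  n <- nrow(xy)
  d <- sqrt((xy[, 1] - wrist_mid[1])^2 + (xy[, 2] - wrist_mid[2])^2)
  ord <- order(tip_idx)
  valleys <- matrix(NA_real_, 4, 2)
  vnames <- character(4)
  for (g in 1:4) {
    i0 <- tip_idx[ord[g]]; i1 <- tip_idx[ord[g + 1]]
    seg <- if (i0 <= i1) i0:i1 else c(i0:n, 1:i1)
    j <- seg[which.min(d[seg])]
    valleys[g, ] <- xy[j, ]
    vnames[g] <- paste(FINGER_NAMES[ord[g]], FINGER_NAMES[ord[g + 1]], sep = "_")
  }
  rownames(valleys) <- vnames
  # report in thumb-to-little order
  want <- c("thumb_index", "index_middle", "middle_ring", "ring_little")
  have <- vapply(want, function(w) {
    hit <- which(vnames == w | vnames == paste(rev(strsplit(w, "_")[[1]]), collapse = "_"))
    if (!length(hit)) NA_integer_ else hit[1]
  }, 0L)
  if (anyNA(have)) hm_error("degenerate_geometry", "could not order ground-truth valleys")
  valleys <- valleys[have, , drop = FALSE]
  rownames(valleys) <- want
  list(valleys = valleys, wrist_mid = wrist_mid)
}

#' Write a rendered scene to disk
#'
#' Saves the image as PNG and the ground truth as a JSON side-car file
#' (same path with extension `.json`).
#'
#' @param scene_render Result of [render_scene()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene_render, path) {
  EBImage::writeImage(EBImage::Image(scene_render$image), path, type = "png")
  gt <- scene_render$ground_truth
  gt$calibration <- list(H_px2mm = gt$calibration$H_px2mm)
  jsonlite::write_json(gt, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
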