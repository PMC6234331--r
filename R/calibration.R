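# Paper detection and pixel-to-millimetre calibration.
#
# The letter-size sheet is found as the dominant quadrilateral in a Hough
# line accumulator over the image gradient: four line peaks grouped into
# two near-perpendicular pairs, refined by total-least-squares on the
# supporting edge pixels, intersected into corners.  The four corners are
# paired with the known 215.9 x 279.4 mm paper rectangle to give an exact
# projective calibration, after which pixel distances anywhere on the
# paper plane convert to millimetres.

new_calibration <- function(H_px2mm, H_mm2px = NULL, aspect_mismatch = NA_real_) {
  if (is.null(H_mm2px)) H_mm2px <- solve(H_px2mm)
  ctr_px <- apply_homography(H_mm2px, matrix(PAPER_MM / 2, 1))
  m0 <- apply_homography(H_px2mm, ctr_px)
  m1 <- apply_homography(H_px2mm, ctr_px + c(1, 0))
  m2 <- apply_homography(H_px2mm, ctr_px + c(0, 1))
  scale <- sqrt(abs(cross2(m1 - m0, m2 - m0)))
  structure(list(H_px2mm = H_px2mm, H_mm2px = H_mm2px,
                 paper_mm = PAPER_MM,
                 center_scale_mm_per_px = as.numeric(scale),
                 aspect_mismatch = aspect_mismatch),
            class = "calibration_model")
}

#' Map image pixels to paper-plane millimetres (and back)
#'
#' @param cal A `calibration_model`.
#' @param pts n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of mapped points.
#' @export
px_to_mm <- function(cal, pts) apply_homography(cal$H_px2mm, pts)

#' @rdname px_to_mm
#' @export
mm_to_px <- function(cal, pts) apply_homography(cal$H_mm2px, pts)

#' Physical distance between two image points
#'
#' Maps both pixel points through the calibration and returns their
#' Euclidean separation on the paper plane in millimetres.
#'
#' @param cal A `calibration_model` from [compute_calibration()].
#' @param p1_px,p2_px Length-2 pixel coordinates.
#' @return Distance in mm.
#' @examples
#' quad <- rbind(c(0, 0), c(2159, 0), c(2159, 2794), c(0, 2794))
#' cal <- compute_calibration(quad)
#' distance_mm(cal, c(100, 100), c(100, 200))  # 10 mm at 0.1 mm/px
#' @export
distance_mm <- function(cal, p1_px, p2_px) {
  m <- px_to_mm(cal, rbind(p1_px, p2_px))
  sqrt(sum((m[1, ] - m[2, ])^2))
}

#' Projective calibration from four paper corners
#'
#' Computes the exact four-point homography mapping the detected corners
#' (ordered top-left, top-right, bottom-right, bottom-left; the
#' wrist-crossed edge is "bottom") onto the canonical letter rectangle,
#' 215.9 x 279.4 mm.  By construction the corners map to the canonical
#' corners to machine precision.
#'
#' @param quad A `quad_detection` from [detect_paper_quad()], or a 4 x 2
#'   pixel matrix in TL, TR, BR, BL order.
#' @return A `calibration_model`.
#' @export
compute_calibration <- function(quad) {
  corners <- if (inherits(quad, "quad_detection")) quad$corners else as_points(quad)
  if (nrow(corners) != 4) hm_error("degenerate_quad", "need exactly 4 corners")
  A <- abs(shoelace_area(corners))
  per <- sum(sqrt(rowSums((corners - corners[c(2:4, 1), ])^2)))
  if (A < 1e-6 || A / per^2 < 1e-3)
    hm_error("degenerate_quad", "corners are (nearly) collinear")
  dst <- rbind(c(0, 0), c(PAPER_MM[1], 0), PAPER_MM, c(0, PAPER_MM[2]))
  H <- homography_from_quad(corners, dst)
  resid <- max(abs(apply_homography(H, corners) - dst))
  if (resid > 1e-6)
    hm_error("degenerate_quad", sprintf("homography residual %.2g mm", resid))
  sides <- sqrt(rowSums((corners[c(2:4, 1), ] - corners)^2))
  long <- mean(sides[c(2, 4)]); short <- mean(sides[c(1, 3)])
  aspect <- max(long, short) / min(long, short)
  new_calibration(H, aspect_mismatch = abs(aspect - PAPER_MM[2] / PAPER_MM[1]) /
                    (PAPER_MM[2] / PAPER_MM[1]))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %.4g mm/px at paper centre, aspect mismatch %.1f%%\n",
              x$center_scale_mm_per_px, 100 * x$aspect_mismatch))
  invisible(x)
}

to_gray <- function(image) {
  if (length(dim(image)) == 3) {
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  } else image
}

# Central-difference gradient (images are pre-smoothed by the camera
# blur; a Sobel smoothing stage adds nothing here).
image_gradient <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (img[3:nx, ] - img[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (img[, 3:ny] - img[, 1:(ny - 2)]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

sobel_magnitude <- function(img) image_gradient(img)$mag

ang_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

line_intersection <- function(l1, l2) {
  # lines in normal form (theta deg, rho px): x cos + y sin = rho
  M <- rbind(c(cos(l1[1] * pi / 180), sin(l1[1] * pi / 180)),
             c(cos(l2[1] * pi / 180), sin(l2[1] * pi / 180)))
  if (abs(det(M)) < 1e-6) return(NULL)
  as.vector(solve(M, c(l1[2], l2[2])))
}

point_line_dist <- function(p, line) {
  abs(p[1] * cos(line[1] * pi / 180) + p[2] * sin(line[1] * pi / 180) - line[2])
}

#' Detect the letter-paper quadrilateral
#'
#' Finds the paper as the dominant convex quadrilateral: Sobel gradient ->
#' Hough line accumulator (1 px x 1 degree) -> peak non-maximum
#' suppression -> two near-perpendicular line pairs -> corner
#' intersections, refined by total least squares on each edge's
#' supporting pixels.  Corners are ordered TL, TR, BR, BL with the edge
#' crossed by the hand/wrist as the bottom.
#'
#' @param image Numeric `[x, y]` matrix (or `[x, y, 3]` array) in [0, 1].
#' @param config A [handmetry_config()].
#' @return A `quad_detection`: `corners` (4 x 2), `lines` (4 x 2
#'   theta/rho), `confidence` (per corner, in [0, 1]), `wrist_side_run`
#'   (fraction of the bottom edge occluded by the hand).
#' @export
detect_paper_quad <- function(image, config = handmetry_config()) {
  img <- to_gray(image)
  hc <- config$hough
  nx <- nrow(img); ny <- ncol(img)
  g <- image_gradient(img)
  mag <- g$mag
  # ignore the one-pixel frame (convolution edge effects)
  mag[c(1, nx), ] <- 0; mag[, c(1, ny)] <- 0
  q <- stats::quantile(mag, 0.999, names = FALSE)
  thr <- hc$edge_rel_threshold * q
  idx <- which(mag > thr)
  if (length(idx) < 100) hm_error("no_paper_found", "too few edge pixels")
  ex <- ((idx - 1) %% nx) + 0.5          # pixel-centre coordinates
  ey <- ((idx - 1) %/% nx) + 0.5
  # gradient orientation of each edge pixel (normal direction, degrees mod 180)
  eang <- (atan2(g$gy[idx], g$gx[idx]) * 180 / pi) %% 180
  # cap the vote set for speed (regular thinning keeps determinism)
  cap <- 60000L
  if (length(ex) > cap) {
    keep <- seq(1, length(ex), length.out = cap)
    ex <- ex[keep]; ey <- ey[keep]; eang <- eang[keep]
  }

  thetas <- seq(0, 180 - hc$theta_res_deg, by = hc$theta_res_deg)
  diag_px <- ceiling(sqrt(nx^2 + ny^2))
  nrho <- 2L * diag_px + 1L
  acc <- matrix(0L, length(thetas), nrho)
  for (ti in seq_along(thetas)) {
    th <- thetas[ti] * pi / 180
    r <- round((ex * cos(th) + ey * sin(th)) / hc$rho_res_px)
    acc[ti, ] <- tabulate(r + diag_px + 1L, nbins = nrho)
  }

  peaks <- hough_peaks(acc, thetas, diag_px, hc)
  if (nrow(peaks) < 4) hm_error("no_paper_found", "fewer than 4 consistent lines")

  quad <- choose_quad(peaks, nx, ny, config$paper$aspect_tol, ex, ey)
  if (is.null(quad)) hm_error("no_paper_found", "no convex quadrilateral from Hough lines")

  # refine each side by total least squares on its supporting edge pixels
  ref <- refine_quad(quad, ex, ey, eang)
  corners <- ref$corners; lines <- ref$lines
  if (any(corners[, 1] < -2 | corners[, 1] > nx + 2 |
          corners[, 2] < -2 | corners[, 2] > ny + 2))
    hm_error("no_paper_found", "paper corner outside the image")
  if (!is_convex_quad(corners))
    hm_error("no_paper_found", "detected corners are not convex")

  sides <- sqrt(rowSums((corners[c(2:4, 1), ] - corners)^2))
  p1 <- mean(sides[c(1, 3)]); p2 <- mean(sides[c(2, 4)])
  aspect <- max(p1, p2) / min(p1, p2)
  target <- PAPER_MM[2] / PAPER_MM[1]
  if (abs(aspect - target) / target > config$paper$aspect_tol)
    hm_error("no_paper_found",
             sprintf("aspect ratio %.3f outside %.0f%% of %.3f (rule 1 or 4 violated?)",
                     aspect, 100 * config$paper$aspect_tol, target))

  # post-refinement support check with the tight band: at most one edge
  # (the wrist-occluded one) may fall below full support
  supp <- quad_side_support(ref$corners, ex, ey)
  if (sort(supp)[2] < 0.55 || min(supp) < 0.4)
    hm_error("no_paper_found", "detected quadrilateral lacks edge support")

  ord <- order_corners(corners, img, sides)
  structure(list(corners = ord$corners, lines = lines,
                 confidence = ref$confidence[ord$perm],
                 wrist_side_run = ord$run),
            class = "quad_detection")
}

hough_peaks <- function(acc, thetas, diag_px, hc) {
  nth <- nrow(acc); nrho <- ncol(acc)
  wth <- round(hc$nms_theta_deg / hc$theta_res_deg)
  wrho <- round(hc$nms_rho_px / hc$rho_res_px)
  out <- matrix(0, 0, 3)
  for (k in seq_len(hc$n_peaks)) {
    m <- which.max(acc)
    v <- acc[m]
    if (v < 30) break
    ti <- ((m - 1) %% nth) + 1
    ri <- ((m - 1) %/% nth) + 1
    out <- rbind(out, c(thetas[ti], (ri - diag_px - 1) * hc$rho_res_px, v))
    for (dt in -wth:wth) {
      t2 <- ti + dt
      flip <- FALSE
      if (t2 < 1) { t2 <- t2 + nth; flip <- TRUE }
      if (t2 > nth) { t2 <- t2 - nth; flip <- TRUE }
      rc <- if (flip) 2 * (diag_px + 1) - ri else ri
      # a line re-expressed at a neighbouring theta pivots: its rho can
      # shift by up to ~(half line length) * sin(dtheta)
      w2 <- wrho + ceiling(abs(dt) * hc$theta_res_deg * pi / 180 * diag_px / 2)
      lo <- max(1, rc - w2); hi <- min(nrho, rc + w2)
      if (lo <= hi) acc[t2, lo:hi] <- 0L
    }
  }
  colnames(out) <- c("theta", "rho", "votes")
  out
}

# Enumerate line-pair combinations from the two near-perpendicular groups
# and keep the largest convex quadrilateral with letter-paper aspect:
# interior hand/wrist edges form smaller or wrongly proportioned quads.
choose_quad <- function(peaks, nx, ny, aspect_tol = 0.10,
                        ex = NULL, ey = NULL) {
  th0 <- peaks[1, "theta"]
  grpA <- peaks[ang_diff(peaks[, "theta"], th0) <= 30, , drop = FALSE]
  grpB <- peaks[ang_diff(peaks[, "theta"], th0 + 90) <= 30, , drop = FALSE]
  grpA <- grpA[seq_len(min(6, nrow(grpA))), , drop = FALSE]
  grpB <- grpB[seq_len(min(6, nrow(grpB))), , drop = FALSE]
  if (nrow(grpA) < 2 || nrow(grpB) < 2) return(NULL)
  target <- PAPER_MM[2] / PAPER_MM[1]
  best <- NULL; best_area <- 0.2 * nx * ny
  for (i in seq_len(nrow(grpA) - 1)) for (j in (i + 1):nrow(grpA))
    for (k in seq_len(nrow(grpB) - 1)) for (l in (k + 1):nrow(grpB)) {
      c1 <- line_intersection(grpA[i, ], grpB[k, ])
      c2 <- line_intersection(grpA[i, ], grpB[l, ])
      c3 <- line_intersection(grpA[j, ], grpB[l, ])
      c4 <- line_intersection(grpA[j, ], grpB[k, ])
      if (is.null(c1) || is.null(c2) || is.null(c3) || is.null(c4)) next
      corners <- rbind(c1, c2, c3, c4)
      if (!is_convex_quad(corners)) next
      area <- abs(shoelace_area(corners))
      if (area <= best_area) next
      sides <- sqrt(rowSums((corners[c(2:4, 1), ] - corners)^2))
      p1 <- mean(sides[c(1, 3)]); p2 <- mean(sides[c(2, 4)])
      aspect <- max(p1, p2) / min(p1, p2)
      if (abs(aspect - target) / target > aspect_tol) next
      # every side of the real sheet is supported by edge pixels along
      # most of its length (the wrist occludes at most part of one edge);
      # phantom quads borrowing hand/wrist lines are not
      if (!is.null(ex) && min(quad_side_support(corners, ex, ey)) < 0.45) next
      best_area <- area
      best <- list(corners = corners,
                   lines = rbind(grpA[i, 1:2], grpB[l, 1:2],
                                 grpA[j, 1:2], grpB[k, 1:2]))
    }
  best
}

# Fraction of each quad side's length covered by nearby edge pixels.
# The band widens with side length: pre-refinement lines carry the Hough
# accumulator's 1-degree quantization, which bows a long edge out of a
# narrow band.
quad_side_support <- function(corners, ex, ey) {
  vapply(1:4, function(i) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    d <- b - a; len <- sqrt(sum(d^2)); dn <- d / len
    t <- (ex - a[1]) * dn[1] + (ey - a[2]) * dn[2]
    perp <- abs((ex - a[1]) * -dn[2] + (ey - a[2]) * dn[1])
    sel <- perp < 2.5 + 0.01 * len & t > 0 & t < len
    length(unique(floor(t[sel]))) / max(1, len)
  }, 0)
}

is_convex_quad <- function(corners) {
  s <- numeric(4)
  for (i in 1:4) {
    e1 <- corners[(i %% 4) + 1, ] - corners[i, ]
    e2 <- corners[((i + 1) %% 4) + 1, ] - corners[(i %% 4) + 1, ]
    s[i] <- sign(cross2(e1, e2))
  }
  all(s == s[1]) && all(s != 0)
}

refine_quad <- function(quad, ex, ey, eang) {
  corners <- quad$corners
  lines <- quad$lines
  conf <- numeric(4)
  for (it in 1:3) {
    newlines <- lines
    for (i in 1:4) {
      a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
      d <- b - a; len <- sqrt(sum(d^2)); dn <- d / len
      t <- (ex - a[1]) * dn[1] + (ey - a[2]) * dn[2]
      perp <- abs((ex - a[1]) * -dn[2] + (ey - a[2]) * dn[1])
      # keep pixels whose gradient points along the side's normal: this
      # rejects contamination where the hand boundary meets the edge
      nrm_ang <- (atan2(dn[1], -dn[2]) * 180 / pi) %% 180
      sel <- perp < 2.5 & t > 12 & t < len - 12 & ang_diff(eang, nrm_ang) < 20
      conf[i] <- min(1, sum(sel) / max(1, len - 24))
      if (sum(sel) >= 30) {
        x <- ex[sel]; y <- ey[sel]
        mx <- mean(x); my <- mean(y)
        C <- stats::cov(cbind(x, y))
        ev <- eigen(C, symmetric = TRUE)
        dir <- ev$vectors[, 1]
        nrm <- c(-dir[2], dir[1])
        theta <- (atan2(nrm[2], nrm[1]) * 180 / pi) %% 180
        rho <- mx * cos(theta * pi / 180) + my * sin(theta * pi / 180)
        newlines[i, ] <- c(theta, rho)
      }
    }
    lines <- newlines
    for (i in 1:4) {
      # corner i+1 is the intersection of sides i and i+1
      q <- line_intersection(lines[i, ], lines[(i %% 4) + 1, ])
      if (!is.null(q)) corners[(i %% 4) + 1, ] <- q
    }
  }
  # corner i joins sides i-1 and i (cyclically); take the weaker support
  cc <- vapply(1:4, function(i) min(conf[((i + 2) %% 4) + 1], conf[i]), 0)
  list(corners = corners, lines = lines, confidence = cc)
}

bilinear_sample <- function(img, pts) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- pmin(pmax(pts[, 1] + 0.5, 1), nx)
  fy <- pmin(pmax(pts[, 2] + 0.5, 1), ny)
  x0 <- pmin(floor(fx), nx - 1); y0 <- pmin(floor(fy), ny - 1)
  ax <- fx - x0; ay <- fy - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  img[i00] * (1 - ax) * (1 - ay) + img[i10] * ax * (1 - ay) +
    img[i01] * (1 - ax) * ay + img[i11] * ax * ay
}

# Identify the paper edge crossed by the hand/wrist (its dark run) and
# order corners so that edge maps to the bottom of the canonical frame.
order_corners <- function(corners, img, sides) {
  nsamp <- 60
  centroid <- colMeans(corners)
  runs <- numeric(4)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    tt <- seq(0.12, 0.88, length.out = nsamp)
    p <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    inward <- 0.04 * min(sides)
    dirc <- centroid - (a + b) / 2
    dirc <- dirc / sqrt(sum(dirc^2))
    p <- sweep(p, 2, -inward * dirc)
    v <- bilinear_sample(img, p)
    paper_level <- stats::median(v)
    dark <- v < 0.75 * paper_level
    r <- rle(dark)
    runs[i] <- if (any(r$values)) max(r$lengths[r$values]) / nsamp else 0
  }
  short_pair <- if (mean(sides[c(1, 3)]) < mean(sides[c(2, 4)])) c(1, 3) else c(2, 4)
  cand <- short_pair[which.max(runs[short_pair])]
  if (runs[cand] < 0.05) {
    # no hand found on either short edge: pick the lower one (deterministic)
    mid_y <- vapply(short_pair, function(i)
      (corners[i, 2] + corners[(i %% 4) + 1, 2]) / 2, 0)
    cand <- short_pair[which.max(mid_y)]
  }
  # side `cand` joins corners cand -> cand+1; two cyclic labelings possible,
  # keep the one whose TL,TR,BR,BL traversal has positive signed area
  # (a physical camera never mirrors the paper)
  i <- cand; i1 <- (i %% 4) + 1; i2 <- ((i + 1) %% 4) + 1; i3 <- ((i + 2) %% 4) + 1
  perm1 <- c(i2, i3, i, i1)   # TL TR BR BL
  perm2 <- c(i3, i2, i1, i)
  perm <- if (shoelace_area(corners[perm1, ]) > 0) perm1 else perm2
  ordered <- corners[perm, ]
  rownames(ordered) <- c("TL", "TR", "BR", "BL")
  list(corners = ordered, perm = perm, run = runs[cand])
}

#' Validate the four capture requirements
#'
#' Checks the four photograph rules the analysis depends on:
#' (1) all four paper corners visible, (2) the hand within the paper's
#' edges (the silhouette may cross only the designated wrist edge),
#' (3) fingers spread (five fingertips with sufficiently deep
#' interdigital valleys), and (4) the background darker than the paper
#' and free of clutter (median intensity outside the quad strictly below
#' the median inside).  Validation never throws: every internal failure
#' is reported as the corresponding rule violation.
#'
#' @param image Image matrix/array in [0, 1].
#' @param quad A `quad_detection`, or `NULL` if detection failed (rule 1).
#' @param config A [handmetry_config()].
#' @return A `capture_validation`: named logical `checks`, character
#'   `violations`, scalar `valid`.
#' @export
validate_capture <- function(image, quad = NULL, config = handmetry_config()) {
  checks <- c(four_corners_visible = TRUE, hand_within_edges = TRUE,
              fingers_spread = TRUE, background_darker_uncluttered = TRUE)
  violations <- character()
  img <- to_gray(image)
  nx <- nrow(img); ny <- ncol(img)

  if (is.null(quad)) {
    checks["four_corners_visible"] <- FALSE
    violations <- c(violations, "paper quadrilateral not detected (rule 1)")
  } else {
    co <- quad$corners
    if (any(co[, 1] < -0.5 | co[, 1] > nx + 0.5 | co[, 2] < -0.5 | co[, 2] > ny + 0.5)) {
      checks["four_corners_visible"] <- FALSE
      violations <- c(violations, "a paper corner lies outside the image (rule 1)")
    }
  }

  if (!is.null(quad) && checks["four_corners_visible"]) {
    # rule 4: median intensity outside the quad vs inside
    step <- max(1L, floor(min(nx, ny) / 200))
    gx <- seq(1L, nx, by = step); gy <- seq(1L, ny, by = step)
    pts <- cbind(rep(gx - 0.5, times = length(gy)), rep(gy - 0.5, each = length(gx)))
    inside <- points_in_polygon(pts, quad$corners)
    vals <- img[cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))]
    if (sum(!inside) > 10 && sum(inside) > 10 &&
        stats::median(vals[!inside]) >= stats::median(vals[inside])) {
      checks["background_darker_uncluttered"] <- FALSE
      violations <- c(violations, "background not darker than the paper (rule 4)")
    }

    cal <- tryCatch(compute_calibration(quad), error = function(e) NULL)
    mask <- if (is.null(cal)) NULL else
      tryCatch(segment_hand(image, cal, config), error = function(e) e)
    if (is.null(mask) || inherits(mask, "error")) {
      checks["fingers_spread"] <- FALSE
      violations <- c(violations, "no hand silhouette found on the paper (rule 3)")
    } else {
      m <- mask$mask
      side_touch <- sum(m[1, ]) + sum(m[nrow(m), ]) + sum(m[, 1])
      if (side_touch >= 3) {
        checks["hand_within_edges"] <- FALSE
        violations <- c(violations,
                        "hand crosses a paper edge other than the wrist edge (rule 2)")
      }
      lmk <- tryCatch(detect_fingertips_valleys(extract_boundary(mask, config), config),
                      error = function(e) e)
      if (inherits(lmk, "error")) {
        checks["fingers_spread"] <- FALSE
        violations <- c(violations,
                        paste0("fingers not spread (rule 3): ", conditionMessage(lmk)))
      }
    }
  }
  structure(list(checks = checks, violations = violations,
                 valid = all(checks)), class = "capture_validation")
}

#' @export
print.capture_validation <- function(x, ...) {
  cat("<capture_validation>", if (x$valid) "VALID" else "INVALID", "\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-32s %s\n", nm, if (x$checks[nm]) "ok" else "VIOLATED"))
  invisible(x)
}

#' @export
print.quad_detection <- function(x, ...) {
  cat("<quad_detection>\n")
  print(round(x$corners, 2))
  cat(sprintf("corner confidence: %s; wrist-edge occlusion %.0f%%\n",
              paste(sprintf("%.2f", x$confidence), collapse = ", "),
              100 * x$wrist_side_run))
  invisible(x)
}
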