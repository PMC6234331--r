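# Hand segmentation in the rectified (calibrated) paper frame.
#
# Segmentation happens after calibration: the paper interior is resampled
# into the canonical mm frame at a fixed working resolution, the hand is
# separated from the white paper by an automatic bimodal intensity
# threshold (Otsu), cleaned by morphological opening/closing at the 1 mm
# scale, and reduced to the single connected component that crosses the
# wrist (bottom) edge.

#' Rectify the paper interior into the canonical mm frame
#'
#' @param image Numeric `[x, y]` matrix (or RGB array) in [0, 1].
#' @param cal A `calibration_model`.
#' @param res Output resolution in pixels per mm.
#' @return List with `img` (rectified `[x, y]` matrix covering
#'   215.9 x 279.4 mm) and `res`.
#' @export
rectify_paper <- function(image, cal, res = 5) {
  img <- to_gray(image)
  nx <- round(PAPER_MM[1] * res); ny <- round(PAPER_MM[2] * res)
  xs <- ((seq_len(nx)) - 0.5) / res
  ys <- ((seq_len(ny)) - 0.5) / res
  mm <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  px <- mm_to_px(cal, mm)
  list(img = matrix(bilinear_sample(img, px), nx, ny), res = res)
}

#' Segment the hand from the paper background
#'
#' Within the rectified paper interior, foreground is every pixel darker
#' than an automatically chosen global threshold (Otsu's bimodal split,
#' which makes the result invariant to global brightness offsets), after
#' morphological opening and closing with a disc of about 1 mm radius.
#' Only the largest component touching the wrist (bottom) edge is kept;
#' specks of clutter and disconnected debris are discarded.
#'
#' @param image Image matrix/array in [0, 1].
#' @param cal A `calibration_model` from [compute_calibration()].
#' @param config A [handmetry_config()].
#' @return A `hand_mask`: logical `[x, y]` matrix in the canonical frame
#'   plus `res` (px/mm) and the area in cm^2.
#' @export
segment_hand <- function(image, cal, config = handmetry_config()) {
  sc <- config$segmentation
  rect <- rectify_paper(image, cal, res = sc$work_res_px_per_mm)
  res <- rect$res
  # Otsu start, then isodata refinement: the midpoint of the class means
  # localizes a blurred edge at its true 50% crossing, which keeps the
  # boundary (and so every mm measurement) stable across capture
  # resolution and blur
  thr <- EBImage::otsu(EBImage::Image(rect$img))
  for (i in 1:8) {
    lo <- rect$img[rect$img < thr]; hi <- rect$img[rect$img >= thr]
    if (!length(lo) || !length(hi)) break
    thr2 <- (mean(lo) + mean(hi)) / 2
    if (abs(thr2 - thr) < 1e-4) { thr <- thr2; break }
    thr <- thr2
  }
  fg <- rect$img < thr
  rad <- max(1L, round(sc$morph_radius_mm * res))
  brush <- EBImage::makeBrush(2L * rad + 1L, "disc")
  fg <- EBImage::closing(EBImage::opening(EBImage::Image(fg * 1), brush), brush) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labd <- EBImage::imageData(lab)
  if (max(labd) == 0) hm_error("no_hand_found", "no foreground on the paper")
  ny <- ncol(labd)
  wrist_labels <- setdiff(unique(labd[, ny]), 0)
  if (!length(wrist_labels))
    hm_error("no_hand_found", "no foreground component reaches the wrist edge")
  sizes <- tabulate(labd, nbins = max(labd))
  keep <- wrist_labels[which.max(sizes[wrist_labels])]
  mask <- labd == keep
  area_cm2 <- sum(mask) / res^2 / 100
  if (area_cm2 < sc$min_hand_area_cm2)
    hm_error("no_hand_found",
             sprintf("largest wrist-touching component is %.1f cm^2 (< %g cm^2)",
                     area_cm2, sc$min_hand_area_cm2))
  structure(list(mask = mask, res = res, area_cm2 = area_cm2,
                 threshold = as.numeric(thr), gray = rect$img),
            class = "hand_mask")
}

#' Extract the calibrated hand boundary polygon
#'
#' Traces the outer contour of the mask, converts it to millimetres,
#' smooths it with a moving average of about 2 mm arc length and
#' resamples it at 0.5 mm spacing.  The wrist chord is the pair of
#' extreme contour points on the bottom paper edge (absent for masks that
#' do not reach it).
#'
#' @param mask A `hand_mask` (or any logical `[x, y]` matrix plus `res`
#'   attribute-compatible list).
#' @param config A [handmetry_config()].
#' @return A `hand_boundary`: `xy` (n x 2 mm, positively oriented,
#'   starting at the wrist), `arc` (cumulative arc length), `wrist_chord`
#'   (2 x 2 or NULL), `area_mm2`, `perimeter_mm`.
#' @export
extract_boundary <- function(mask, config = handmetry_config()) {
  sc <- config$segmentation
  res <- mask$res
  oc <- EBImage::ocontour(EBImage::Image(mask$mask * 1))
  k <- which.max(vapply(oc, nrow, 0L))
  xy <- (oc[[k]] + 0.5) / res
  if (nrow(xy) < 20) hm_error("no_hand_found", "degenerate contour")
  # uniform fine resampling, subpixel refinement against the gray image
  # (threshold crossing along the local normal), then 2 mm circular
  # smoothing and 0.5 mm resampling
  fine <- 0.25
  xy <- resample_polyline(xy, fine, closed = TRUE)
  if (!is.null(mask$gray) && !is.null(mask$threshold))
    xy <- refine_boundary_subpixel(xy, mask$gray, res, mask$threshold)
  xy <- smooth_closed(xy, round(sc$smooth_window_mm / fine))
  xy <- resample_polyline(xy, sc$resample_mm, closed = TRUE)
  if (shoelace_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]

  ny_mm <- ncol(mask$mask) / res
  on_bottom <- xy[, 2] > ny_mm - (2 / res)
  wrist_chord <- NULL
  if (any(on_bottom)) {
    xs <- xy[on_bottom, 1]
    wrist_chord <- rbind(c(min(xs), ny_mm), c(max(xs), ny_mm))
    # start traversal at the wrist
    start <- which(on_bottom)[1]
    if (start > 1) xy <- xy[c(start:nrow(xy), 1:(start - 1)), , drop = FALSE]
  }
  arc <- polyline_arc(xy, closed = TRUE)
  structure(list(xy = xy, arc = arc[-length(arc)],
                 perimeter_mm = arc[length(arc)],
                 area_mm2 = abs(shoelace_area(xy)),
                 wrist_chord = wrist_chord),
            class = "hand_boundary")
}

# Move each boundary vertex along its local normal to the exact
# threshold crossing of the gray image (linear interpolation between
# bilinear samples).  The binary contour is quantized to the working
# pixel grid; the gray image localizes the edge to a fraction of it.
refine_boundary_subpixel <- function(xy, gray, res, thr, reach_mm = 0.8) {
  n <- nrow(xy)
  im <- c(n, 1:(n - 1)); ip <- c(2:n, 1)
  tx <- xy[ip, 1] - xy[im, 1]; ty <- xy[ip, 2] - xy[im, 2]
  tl <- sqrt(tx^2 + ty^2); tl[tl < 1e-9] <- 1
  nxv <- -ty / tl; nyv <- tx / tl
  ts <- seq(-reach_mm, reach_mm, by = 0.1)
  vals <- matrix(NA_real_, n, length(ts))
  for (k in seq_along(ts)) {
    px <- cbind((xy[, 1] + ts[k] * nxv) * res, (xy[, 2] + ts[k] * nyv) * res)
    vals[, k] <- bilinear_sample(gray, px)
  }
  s <- vals - thr
  off <- numeric(n)
  mid <- which.min(abs(ts))
  for (i in seq_len(n)) {
    cr <- which(s[i, -1] * s[i, -length(ts)] <= 0)
    if (!length(cr)) next
    k <- cr[which.min(abs(ts[cr] + 0.05))]
    d <- s[i, k + 1] - s[i, k]
    off[i] <- if (abs(d) > 1e-12) ts[k] + 0.1 * (-s[i, k] / d) else ts[k]
  }
  cbind(xy[, 1] + off * nxv, xy[, 2] + off * nyv)
}

#' @export
print.hand_boundary <- function(x, ...) {
  cat(sprintf("<hand_boundary> %d vertices, perimeter %.1f mm, area %.1f cm^2%s\n",
              nrow(x$xy), x$perimeter_mm, x$area_mm2 / 100,
              if (is.null(x$wrist_chord)) "" else ", wrist chord present"))
  invisible(x)
}
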