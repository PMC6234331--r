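# Planar geometry primitives shared by the renderer and the measurement
# pipeline.  Conventions: points are n x 2 matrices (x, y); pixel
# coordinates are continuous with the centre of pixel (i, j) at
# (i - 0.5, j - 0.5); image matrices are indexed [x, y] (EBImage layout);
# millimetre coordinates live in the canonical portrait paper frame with
# the origin at the top-left corner, x along the 215.9 mm edge and y along
# the 279.4 mm edge.

PAPER_MM <- c(215.9, 279.4)

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  p
}

#' @noRd
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) hm_error("degenerate_geometry", "zero-length direction vector")
  v / n
}

vec_angle_deg <- function(a, b) {
  # unsigned angle between direction vectors, in [0, 180)
  atan2(abs(cross2(a, b)), sum(a * b)) * 180 / pi
}

signed_angle_deg <- function(a, b) {
  # CCW-positive rotation carrying a onto b
  atan2(cross2(a, b), sum(a * b)) * 180 / pi
}

# Apply a 3x3 homography to an n x 2 point matrix.
apply_homography <- function(H, pts) {
  pts <- as_points(pts)
  w <- H[3, 1] * pts[, 1] + H[3, 2] * pts[, 2] + H[3, 3]
  x <- (H[1, 1] * pts[, 1] + H[1, 2] * pts[, 2] + H[1, 3]) / w
  y <- (H[2, 1] * pts[, 1] + H[2, 2] * pts[, 2] + H[2, 3]) / w
  cbind(x, y, deparse.level = 0)
}

# Exact 4-point homography (DLT with the 8-parameter normalization h33 = 1).
homography_from_quad <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    hm_error("degenerate_quad", "cannot solve homography: corners nearly collinear"))
  matrix(c(h[1:3], h[4:6], h[7:8], 1), 3, 3, byrow = TRUE)
}

shoelace_area <- function(xy) {
  # signed area; positive for the package's canonical traversal orientation
  xy <- as_points(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polyline_arc <- function(xy, closed = FALSE) {
  xy <- as_points(xy)
  if (closed) xy <- rbind(xy, xy[1, ])
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(d))
}

# Resample an open or closed polyline at uniform arc spacing.
resample_polyline <- function(xy, spacing, closed = FALSE) {
  xy <- as_points(xy)
  arc <- polyline_arc(xy, closed = closed)
  total <- arc[length(arc)]
  pts <- if (closed) rbind(xy, xy[1, ]) else xy
  n <- max(if (closed) 8L else 2L, round(total / spacing))
  s <- if (closed) seq(0, total, length.out = n + 1)[-(n + 1)] else seq(0, total, length.out = n)
  cbind(stats::approx(arc, pts[, 1], xout = s)$y,
        stats::approx(arc, pts[, 2], xout = s)$y)
}

# Circular moving average smoothing of a closed polygon, window in points.
smooth_closed <- function(xy, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1L) return(xy)
  n <- nrow(xy)
  k <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -k:k, function(i, j) ((i + j - 1) %% n) + 1)
  cbind(rowMeans(matrix(xy[idx, 1], n)), rowMeans(matrix(xy[idx, 2], n)))
}

smooth_open <- function(xy, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1L || nrow(xy) < window) return(xy)
  k <- (window - 1L) %/% 2L
  n <- nrow(xy)
  idx <- outer(seq_len(n), -k:k, function(i, j) pmin(pmax(i + j, 1L), n))
  cbind(rowMeans(matrix(xy[idx, 1], n)), rowMeans(matrix(xy[idx, 2], n)))
}

# Point-in-polygon (even-odd rule), vectorized over query points.
points_in_polygon <- function(pts, poly) {
  pts <- as_points(pts); poly <- as_points(poly)
  n <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# All parameters t where the line p + t * d crosses the closed polygon.
polygon_line_crossings <- function(poly, p, d) {
  poly <- as_points(poly)
  a <- poly
  b <- poly[c(2:nrow(poly), 1), ]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  denom <- d[1] * ey - d[2] * ex
  ok <- abs(denom) > 1e-12
  rx <- a[, 1] - p[1]; ry <- a[, 2] - p[2]
  t <- (rx * ey - ry * ex) / denom
  u <- (rx * d[2] - ry * d[1]) / denom
  sort(t[ok & u >= 0 & u < 1])
}

# The chord of `poly` through p along direction d that contains p,
# or NULL if p is outside.  Returns list(a, b, length, mid).
polygon_chord <- function(poly, p, d) {
  t <- polygon_line_crossings(poly, p, d)
  if (length(t) < 2) return(NULL)
  lo <- t[t <= 0]; hi <- t[t > 0]
  if (!length(lo) || !length(hi)) return(NULL)
  # even-odd: p must be inside, i.e. an odd number of crossings on each side
  if (length(lo) %% 2 == 0 || length(hi) %% 2 == 0) return(NULL)
  t0 <- max(lo); t1 <- min(hi)
  a <- p + t0 * d; b <- p + t1 * d
  list(a = a, b = b, length = t1 - t0, mid = (a + b) / 2)
}

# Scanline fill of a simple polygon into a logical [x, y] raster at `res`
# pixels per mm; raster covers [0, nx/res] x [0, ny/res].
rasterize_polygon <- function(poly, res, nx, ny) {
  poly <- as_points(poly)
  m <- matrix(FALSE, nx, ny)
  a <- poly
  b <- poly[c(2:nrow(poly), 1), ]
  for (j in seq_len(ny)) {
    yc <- (j - 0.5) / res
    crosses <- (a[, 2] > yc) != (b[, 2] > yc)
    if (!any(crosses)) next
    xs <- a[crosses, 1] + (yc - a[crosses, 2]) *
      (b[crosses, 1] - a[crosses, 1]) / (b[crosses, 2] - a[crosses, 2])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      i0 <- max(1L, ceiling(xs[k] * res + 0.5))
      i1 <- min(nx, floor(xs[k + 1] * res + 0.5))
      if (i0 <= i1) m[i0:i1, j] <- TRUE
    }
  }
  m
}

# Directed Hausdorff distance between two point sets (max over a of min over b).
hausdorff_points <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  # chunked to keep memory bounded
  mx <- 0
  idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / 2000))
  for (ii in idx) {
    d2 <- outer(a[ii, 1], b[, 1], "-")^2 + outer(a[ii, 2], b[, 2], "-")^2
    mx <- max(mx, sqrt(max(apply(d2, 1, min))))
  }
  mx
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

# Separable Gaussian blur with edge clamping (direct shift-add; faster
# than FFT convolution at these kernel sizes).
gaussian_blur_sep <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(0, nx, ny)
  for (k in seq_along(w)) {
    idx <- pmin(pmax(seq_len(nx) + (k - r - 1L), 1L), nx)
    out <- out + w[k] * img[idx, ]
  }
  img <- out; out <- matrix(0, nx, ny)
  for (k in seq_along(w)) {
    idx <- pmin(pmax(seq_len(ny) + (k - r - 1L), 1L), ny)
    out <- out + w[k] * img[, idx]
  }
  out
}
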