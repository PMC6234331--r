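#' Pipeline configuration
#'
#' Every threshold of the measurement pipeline is collected in one nested
#' list so that unstated tuning constants are visible and overridable.
#' Values are in the units stated; lengths are millimetres unless the name
#' says pixels.
#'
#' @param ... Named overrides, using nested lists (e.g.
#'   `segmentation = list(work_res_px_per_mm = 4)`).  Unnamed structure is
#'   merged recursively over the defaults.
#' @param file Optional path to a YAML file of overrides, applied before
#'   `...`.
#' @return A nested list with class `handmetry_config`.
#' @examples
#' cfg <- handmetry_config(flags = list(swelling_mm = 1.5))
#' cfg$flags$swelling_mm
#' @export
handmetry_config <- function(..., file = NULL) {
  defaults <- list(
    paper = list(
      size_mm = c(215.9, 279.4),       # US letter, portrait
      aspect_tol = 0.10                # rectified aspect-ratio tolerance
    ),
    hough = list(
      rho_res_px = 1,                  # accumulator resolution
      theta_res_deg = 1,
      nms_theta_deg = 5,               # peak non-maximum suppression window
      nms_rho_px = 10,
      n_peaks = 12,
      edge_rel_threshold = 0.30,       # of robust max gradient magnitude
      max_image_px = 1400              # Hough runs on a decimated image above this
    ),
    segmentation = list(
      work_res_px_per_mm = 5,          # rectified working resolution
      morph_radius_mm = 1,
      min_hand_area_cm2 = 20,
      smooth_window_mm = 2,
      resample_mm = 0.5
    ),
    landmarks = list(
      min_tip_separation_mm = 15,
      min_valley_depth_mm = 5,
      curvature_window_mm = 3,
      tip_refine_arc_mm = 8
    ),
    joints = list(
      dip_window = c(0.15, 0.35),      # fraction of finger length from tip
      pip_window = c(0.40, 0.65),
      thumb_ip_window = c(0.35, 0.70),
      profile_smooth_mm = 1.5,
      min_segment_mm = 4
    ),
    flags = list(
      swelling_mm = 2,                 # joint-thickness increase flagged
      deviation_deg = 3                # |deviation| increase flagged
    )
  )
  cfg <- defaults
  if (!is.null(file)) cfg <- modify_list_rec(cfg, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) cfg <- modify_list_rec(cfg, dots)
  class(cfg) <- c("handmetry_config", "list")
  cfg
}

modify_list_rec <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_rec(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# Stable non-cryptographic hash of a config (djb2 over its JSON form),
# recorded in reports so a measurement is traceable to its thresholds.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
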