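# Shared fixtures: rendered scenes are expensive, so test files draw them
# from a lazy cache.  Everything is generated in code under fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a hand with bends in every measured quantity
bent_hand <- function() {
  h <- default_hand_spec()
  h$fingers$middle$deviation_deg <- c(pip = 12, dip = -6)
  h$fingers$index$deviation_deg <- c(pip = -8, dip = 4)
  h$fingers$thumb$deviation_deg <- c(ip = 7)
  h
}

scene_clean <- function() cached("clean", render_scene(
  default_hand_spec(),
  scene_spec(px_per_mm = 5, rotation_deg = 0, noise_sd = 0, seed = 1)))

scene_rot30 <- function() cached("rot30", render_scene(
  default_hand_spec(),
  scene_spec(px_per_mm = 5, rotation_deg = 30, tilt = c(8e-5, -6e-5),
             noise_sd = 3 / 255, seed = 2)))

scene_rot90 <- function() cached("rot90", render_scene(
  default_hand_spec(),
  scene_spec(px_per_mm = 5, rotation_deg = 90, noise_sd = 0, seed = 3)))

scene_bent <- function() cached("bent", render_scene(
  bent_hand(),
  scene_spec(px_per_mm = 5, rotation_deg = 12, tilt = c(1e-4, -8e-5),
             noise_sd = 3 / 255, seed = 7)))

scene_left <- function() cached("left", {
  h <- bent_hand(); h$handedness <- "left"
  render_scene(h, scene_spec(px_per_mm = 5, rotation_deg = 0, noise_sd = 0, seed = 4))
})

# full measurement pipeline on a rendered scene
run_pipeline <- function(rendered, config = handmetry_config()) {
  cal <- compute_calibration(detect_paper_quad(rendered$image, config))
  mask <- segment_hand(rendered$image, cal, config)
  boundary <- extract_boundary(mask, config)
  lm <- detect_fingertips_valleys(boundary, config)
  list(cal = cal, mask = mask, boundary = boundary, landmarks = lm,
       measurements = measure_hand(boundary, lm, cal, config))
}

pipeline_clean <- function() cached("pipe_clean", run_pipeline(scene_clean()))
pipeline_bent <- function() cached("pipe_bent", run_pipeline(scene_bent()))
pipeline_rot30 <- function() cached("pipe_rot30", run_pipeline(scene_rot30()))
pipeline_rot90 <- function() cached("pipe_rot90", run_pipeline(scene_rot90()))

# image of an empty sheet of paper on a darker background, axis-aligned
paper_only_image <- function(px_per_mm = 5, margin_px = 40) {
  nx <- round(215.9 * px_per_mm) + 2 * margin_px
  ny <- round(279.4 * px_per_mm) + 2 * margin_px
  img <- matrix(0.3, nx, ny)
  img[(margin_px + 1):(nx - margin_px), (margin_px + 1):(ny - margin_px)] <- 0.85
  handmetry:::gaussian_blur_sep(img, 1)
}

# measurements object with prescribed joint thicknesses/deviations, for
# longitudinal tests that do not need the imaging pipeline
make_measurements <- function(thick_shift = c(middle_pip = 0),
                              dev_shift = c(middle_pip = 0)) {
  fingers <- list()
  base_thick <- list(thumb = c(ip = 18),
                     index = c(dip = 15.5, pip = 18),
                     middle = c(dip = 16, pip = 18.5),
                     ring = c(dip = 15, pip = 17.5),
                     little = c(dip = 13.5, pip = 15.5))
  for (fn in names(base_thick)) {
    th <- base_thick[[fn]]
    dv <- stats::setNames(rep(0, length(th)), names(th))
    for (nm in names(thick_shift)) {
      parts <- strsplit(nm, "_")[[1]]
      if (parts[1] == fn) th[parts[2]] <- th[parts[2]] + thick_shift[[nm]]
    }
    for (nm in names(dev_shift)) {
      parts <- strsplit(nm, "_")[[1]]
      if (parts[1] == fn) dv[parts[2]] <- dv[parts[2]] + dev_shift[[nm]]
    }
    fingers[[fn]] <- list(length_mm = 80, joint_arc_mm = th * 0 + 25,
                          thickness_mm = th, angulation_deg = abs(dv),
                          deviation_deg = dv,
                          low_confidence = th > 1e9)
  }
  structure(list(fingers = fingers, palm_width_mm = 85, span_mm = 140,
                 handedness = "right", scale_mm_per_px = 0.2),
            class = "hand_measurements")
}

expect_handmetry_error <- function(expr, class) {
  expect_error(expr, class = paste0("handmetry_", class))
}
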