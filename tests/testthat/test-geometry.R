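test_that("width profile of an analytic constant-width capsule is flat at 16 mm", {
  # stadium: straight sides 80 mm apart in y, radius 8 caps
  r <- 8; L <- 80
  tipc <- c(100, 60); basec <- c(100, 60 + L)
  # right side down, base cap, left side up, tip cap
  ts <- seq(0, 1, length.out = 80)
  right <- cbind(rep(108, 80), 60 + ts * L)
  left <- cbind(rep(92, 80), 60 + (1 - ts) * L)
  cap_base <- cbind(basec[1] + r * cos(seq(0, pi, length.out = 60) * -1 + 0),
                    basec[2] + r * sin(seq(0, pi, length.out = 60)))
  cap_tip <- cbind(tipc[1] + r * cos(seq(pi, 2 * pi, length.out = 60)),
                   tipc[2] + r * sin(seq(pi, 2 * pi, length.out = 60)))
  poly <- rbind(right, cap_base, left, cap_tip)
  boundary <- list(xy = poly)
  centerline <- cbind(rep(100, 100), seq(52, 60 + L, length.out = 100))
  prof <- width_profile(boundary, centerline)
  shaft <- prof$width_mm[prof$arc_mm > r + 1 & prof$arc_mm < r + L - 1]
  expect_true(all(abs(shaft - 16) < 0.3))
  # width shrinks monotonically toward the tip over the final half-width
  cap <- prof[prof$arc_mm < r / 2, ]
  expect_true(all(diff(cap$width_mm) > -1e-9))   # arc runs away from the tip
  expect_true(max(cap$width_mm) < 16 + 0.3)
})

test_that("joints are localized at width bulges, with fallback for bulge-free profiles", {
  L <- 80
  arc <- seq(0, L, by = 0.5)
  w <- 14 + 2.5 * exp(-(arc - 0.25 * L)^2 / 8) + 3 * exp(-(arc - 0.5 * L)^2 / 8)
  prof <- data.frame(arc_mm = arc, width_mm = w)
  j <- locate_joints(prof, L, finger = "index")
  expect_lt(abs(j$arc_mm[["dip"]] - 0.25 * L), 2)
  expect_lt(abs(j$arc_mm[["pip"]] - 0.50 * L), 2)
  expect_false(any(j$low_confidence))

  flat <- data.frame(arc_mm = arc, width_mm = rep(15, length(arc)))
  jf <- locate_joints(flat, L, finger = "index")
  expect_true(all(jf$low_confidence))
  expect_equal(unname(jf$arc_mm[["dip"]]), mean(c(0.15, 0.35)) * L, tolerance = 0.05)
  expect_equal(unname(jf$arc_mm[["pip"]]), mean(c(0.40, 0.65)) * L, tolerance = 0.05)
})

test_that("angulation and signed deviation recover the imposed bends end-to-end", {
  r <- scene_bent()
  mm <- pipeline_bent()$measurements
  gt <- r$ground_truth$measurements
  for (fn in c("index", "middle", "ring", "little")) {
    expect_lt(max(abs(mm$fingers[[fn]]$angulation_deg - gt[[fn]]$angulation_deg)),
              2, label = fn)
    expect_lt(max(abs(mm$fingers[[fn]]$deviation_deg - gt[[fn]]$deviation_deg)),
              2, label = fn)
  }
  # straight fingers give ~0
  mm0 <- pipeline_clean()$measurements
  expect_lt(max(abs(mm0$fingers$ring$angulation_deg)), 1)
  expect_lt(max(abs(mm0$fingers$ring$deviation_deg)), 1)
})

test_that("measurements are invariant to scene rotation", {
  m0 <- as.data.frame(pipeline_clean()$measurements)
  m90 <- as.data.frame(pipeline_rot90()$measurements)
  d <- merge(m0, m90, by = c("finger", "metric"))
  ang <- d[grepl("angulation|deviation", d$metric), ]
  expect_lt(max(abs(ang$value.y - ang$value.x)), 0.5)
  len <- d[grepl("thickness|length|span", d$metric), ]
  expect_lt(max(abs(len$value.y - len$value.x) / pmax(len$value.x, 1)), 0.01)
})

test_that("a mirrored hand flips deviation signs but keeps magnitudes", {
  mmR <- pipeline_bent()$measurements
  mmL <- run_pipeline(scene_left())$measurements
  for (fn in c("index", "middle")) {
    dR <- mmR$fingers[[fn]]$deviation_deg
    dL <- mmL$fingers[[fn]]$deviation_deg
    big <- abs(dR) > 3
    expect_true(all(sign(dL[big]) == sign(dR[big])),  # ulnar-positive on both sides
                info = fn)
    expect_lt(max(abs(abs(dL) - abs(dR))), 1.5)
  }
})

test_that("thickness and length recovery meet tolerance on the bent hand", {
  r <- scene_bent()
  mm <- pipeline_bent()$measurements
  gt <- r$ground_truth$measurements
  for (fn in c("index", "middle", "ring", "little")) {
    terr <- abs(mm$fingers[[fn]]$thickness_mm - gt[[fn]]$thickness_mm)
    expect_true(all(terr < pmax(0.5, 0.03 * gt[[fn]]$thickness_mm)), info = fn)
    expect_lt(abs(mm$fingers[[fn]]$length_mm / gt[[fn]]$length_mm - 1), 0.02,
              label = fn)
  }
  # thumb IP thickness is measured too (length uses the webbing convention)
  expect_lt(abs(mm$fingers$thumb$thickness_mm[["ip"]] -
                gt$thumb$thickness_mm[["ip"]]), 1)
})

test_that("measure_hand is deterministic", {
  pipe <- pipeline_clean()
  m1 <- measure_hand(pipe$boundary, pipe$landmarks, pipe$cal)
  m2 <- measure_hand(pipe$boundary, pipe$landmarks, pipe$cal)
  expect_identical(m1, m2)
})

test_that("doubling capture resolution changes no measurement by more than 0.5%", {
  run <- function(ppm) {
    r <- render_scene(default_hand_spec(),
                      scene_spec(px_per_mm = ppm, rotation_deg = 0,
                                 noise_sd = 0, seed = 1),
                      gt_landmarks = FALSE)
    as.data.frame(run_pipeline(r)$measurements)
  }
  d <- merge(cached("scale5", run(5)), cached("scale10", run(10)),
             by = c("finger", "metric"))
  lin <- d[grepl("thickness|length|span|palm", d$metric), ]
  expect_lt(max(abs(lin$value.y - lin$value.x) / lin$value.x), 0.005)
  ang <- d[grepl("angulation|deviation", d$metric), ]
  expect_lt(max(abs(ang$value.y - ang$value.x)), 0.5)
})
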