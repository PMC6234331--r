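---
title: "Measuring hand geometry from calibrated photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hand geometry from calibrated photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmetry)
```

## The measurement problem

People with rheumatoid arthritis accumulate joint damage between clinic
visits: synovitis thickens the interphalangeal joints, and progressive
deformity drifts the fingers toward the ulnar side. Both changes are
visible in an ordinary photograph of a hand — *if* the photograph can be
converted to physical units. `handmetry` implements the measurement
engine for that task: a letter-size sheet of white paper (215.9 × 279.4
mm) placed under the hand acts as a planar calibration reference, and
every downstream quantity is reported in millimetres and degrees.

The pipeline is:

1. **Paper detection.** Sobel gradient magnitude → Hough line
   accumulator (1 px × 1° resolution) → peak non-maximum suppression →
   two near-perpendicular line pairs → corner intersections, refined by
   total least squares on each edge's supporting pixels
   (`detect_paper_quad()`).
2. **Calibration.** The exact four-point homography mapping the ordered
   corners to the canonical paper rectangle (`compute_calibration()`).
   After this step pixel separations correspond to physical units
   anywhere on the paper plane (`distance_mm()`).
3. **Segmentation.** The paper interior is rectified into the canonical
   frame and the hand separated from the white background by an
   automatic bimodal threshold, cleaned morphologically, and reduced to
   the one component crossing the wrist edge (`segment_hand()`).
4. **Landmarking.** Fingertips and interdigital valleys from the
   boundary polygon; handedness from the thumb side; per-finger
   centerlines as chains of perpendicular-chord midpoints
   (`detect_fingertips_valleys()`, `finger_axes()`).
5. **Geometry.** Width profiles along each centerline; joints localized
   as width bulges inside anatomical windows; joint thickness, segment
   angulation and signed (ulnar-positive) angular deviation
   (`measure_hand()`).
6. **Longitudinal comparison.** Per-metric deltas, swelling and
   deviation-progression flags, recommendation codes
   (`compare_records()`, `series_trend()`).

There is no public image corpus for this capture protocol, so the
package ships a synthetic-scene renderer with exact ground truth
(`render_scene()`), and the whole validation strategy is parameter
recovery against it.

## The synthetic hand and scene model

A hand is a convex palm polygon plus, per finger, a chain of capsule
(stadium) segments whose radius varies piecewise-linearly along the
chain (`hand_spec()`). Non-thumb fingers have three segments with widths
specified at base, PIP, DIP and tip; the thumb has two segments and a
single IP joint. Two modelling choices deserve explanation:

* **Joint bulges.** Between the width knots at the joints, each phalanx
  narrows to a waist of 0.92 × the narrower adjacent joint width. Real
  fingers bulge at the joints, and that bulge is the *only* cue a
  silhouette offers for joint localization; a strictly monotone taper
  would make "joint thickness" unmeasurable from any silhouette, ours or
  a real one. The geometry module's fallback (window midpoint +
  low-confidence flag) covers bulge-free profiles.
* **Spread clearance.** The renderer rejects hands whose adjacent
  fingers come within 2 mm of touching. "Fingers are spread" is one of
  the four stated capture requirements; with clearances below ~1 mm the
  1 mm morphological closing used in segmentation bridges the
  interdigital gap, which is exactly the degraded-capture condition the
  validation stage is supposed to reject, not a condition to measure
  through.

Angles follow one convention everywhere: **ulnar-positive**, i.e. a
positive spread or deviation tilts a finger toward the little-finger
side, the direction of the classic rheumatoid drift. Deviation is
applied at each interphalangeal joint when the chain is built and is
recovered as the signed lateral component of the direction change
between adjacent centerline segments.

The scene model (`scene_spec()`) warps the paper plane by a projective
pose (in-plane rotation, translation, two perspective tilt parameters in
1/mm), lights it with three intensity levels (paper > hand >
background), then applies additive Gaussian noise followed by Gaussian
blur. A seed fully determines the render. Default study conditions used
throughout the tests: 5 px/mm on the paper plane (a 12-megapixel phone
photo at ~60 cm), rotations up to ±30°, tilt parameters up to 2×10⁻⁴/mm
(a few degrees of camera tilt), noise σ up to 5/255, blur σ of 1 px.

What the renderer deliberately does **not** emulate: skin texture and
colour, shadows cast by the hand, rings and sleeves, out-of-plane finger
flexion (the model hand is flat), lens distortion, and non-planar paper.
Passing tests therefore demonstrate correctness of the *geometry
recovery machinery* under the stated capture protocol, not robustness to
every failure mode of real phone photography — on real images the
capture-validation stage is the first line of defence, and flexed or
ring-bearing hands will need the low-confidence flags.

## Ground truth and what "true" means for the thumb

`render_scene()` returns exact paper corners, the true calibration, and
fingertip positions (capsule apexes). Valley and wrist ground truth are
derived from a clean high-resolution silhouette raster of the same
analytic model — they are properties of the rendered shape, not of the
detection pipeline. Per-finger "true" measurements are read directly off
the spec: thickness = the joint width knot, angulation = |deviation|,
length = tip radius + segment lengths.

The thumb needs one convention of its own. Its silhouette base is the
thumb–index webbing, which sits well distal of the skeletal thumb base
on the palm edge; no silhouette method can see the latter. Measured
thumb length therefore runs from the tip to the webbing level
(perpendicular to the thumb's own axis), and the thumb is excluded from
length- and angle-recovery aggregates, while its IP thickness is
recovered and tested like every other joint. The IP search window is
35–70% of the webbing length (fingers: DIP 15–35%, PIP 40–65% of finger
length from the tip).

## Numerical choices

* **Working resolution.** Segmentation and all geometry run in the
  rectified canonical frame at a fixed 5 px/mm, so measurements are
  nearly independent of capture resolution (the scale-equivariance test
  bounds the residual at 0.5%).
* **Threshold.** Otsu's split started the bimodal threshold, refined by
  isodata iteration to the midpoint of the class means — the midpoint
  localizes a blurred edge at its 50% crossing, making the boundary
  stable under blur and brightness offsets.
* **Subpixel boundary.** The binary contour is quantized to the working
  grid (0.2 mm); each vertex is refined along its local normal to the
  exact threshold crossing of the gray rectified image before the 2 mm
  smoothing and 0.5 mm resampling. This removes a ~0.1 mm
  resolution-dependent width bias.
* **Hough peaks.** Non-maximum suppression uses ±5° × ±10 px, widened in
  rho for neighbouring theta bins because a long edge re-expressed one
  degree off pivots its rho by up to half the edge length × sin(1°).
  Quadrilateral selection enumerates pairs from the two perpendicular
  line groups and keeps the largest convex quad whose rectified aspect
  is within 10% of 279.4/215.9 — wrist and finger edges form long lines
  too, but never that quadrilateral.
* **Joint localization.** Inside each anatomical window the bulge is
  taken as the centroid of the width excess around the local maximum
  (the raw argmax jitters on the flat bulge top); thickness is the mean
  width within ±1 mm of the joint.
* **Centerline tracing.** March from the refined tip in 1 mm steps
  through perpendicular-chord midpoints with damped direction updates;
  stop by projecting the last good midpoint onto the finger's base line
  (valley-to-valley chord for interior fingers, the hand-axis plane
  through the single adjacent valley for index and little, the
  thumb-axis plane through the webbing for the thumb). A chord more than
  2.2× the median near-tip width means the trace has escaped into the
  palm and stops it.
* **Degenerate inputs.** Collinear corners raise `degenerate_quad`; an
  empty sheet raises `no_hand_found`; fewer than five fingertip
  candidates or a valley shallower than 5 mm raises
  `fingers_not_spread`; all are classed conditions a caller (and the
  validation stage) can dispatch on.

## Default thresholds

All tunables live in one config object (`handmetry_config()`), YAML-
overridable. The clinically meaningful ones: a swelling flag requires a
joint-thickness increase ≥ 2 mm between valid captures (comfortably
above the ~0.3 mm measurement noise floor but below a clinically obvious
effusion), and a deviation-progression flag requires |deviation| to grow
by ≥ 3°. Both are exposed, not hard-coded, because no published rule
exists for photograph-derived flags; the recommendation codes
(`NO_CHANGE`, `RECHECK_SOON`, `DISCUSS_WITH_CLINICIAN`) are
machine-readable placeholders for a clinician-approved policy, and are
documented as such.

## Problem sizes used in validation

The test-suite study conditions: corner recovery over 50 random scenes
(5–6 px/mm, rotations ±30°, mild tilt, noise up to 5/255) with RMSE
< 1 px; parameter recovery over 30 sampled hands end-to-end (joint
thickness MAE < 1 mm, segment angulation and signed deviation MAE < 2°,
deviation sign 100% correct where |true| ≥ 5°); structural invariants of
the hand sampler over 100 draws; plus rotation/scale invariance and
closed-form boundary checks. These sizes keep the full suite in the
tens of minutes on a single core while estimating MAEs from 240 joints.

## Known limitations

* Flat-hand assumption: out-of-plane flexion shortens fingers by the
  cosine of the flexion angle and is invisible to the method.
* Palm width is measured 8 mm proximal of the valleys, before the thumb
  joins the palm — a proxy for knuckle-line width, biased low by a
  percent or two where the palm tapers.
* The thumb length convention above; thumb angulation/deviation are
  reported but not validated.
* Joint localization needs a visible bulge; a perfectly cylindrical
  finger yields window-midpoint positions with a low-confidence flag.
* Letter paper only by default; other reference sheets would be a
  configuration extension of the same homography machinery.
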