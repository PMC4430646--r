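---
title: "Single-camera markerless gait analysis: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-camera markerless gait analysis: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

gait2d estimates sagittal-plane lower-limb kinematics — hip, knee and
ankle flexion/extension and pelvic tilt — together with gait events and
spatiotemporal parameters, from a single lateral video of a walking
subject. The subject wears white, adherent ankle socks and underwear in
front of a homogeneous blue background; the garments act as *segmental
markers* for the feet and pelvis, while the shank and thigh are tracked
as silhouette segments. No skin-mounted markers and no multi-camera rig
are required, at the price of unilateral (foreground-limb) kinematics
and purely planar angles.

All image-plane geometry lives in the image coordinate system CS_I:
origin at the bottom-left pixel, x along the direction of progression,
y vertical up, units of pixels. The pixel-to-mm scale is obtained from
the measured foot length and the horizontal extent of the foot marker in
the static reference image, so a single anthropometric measurement
calibrates the spatial mapping.

## The subject-specific model

The lower limb is modelled as four segments — foot, tibia, femur,
pelvis — connected by hinges. Each segment carries two frames:

* a *technical* frame CS_T, axis-aligned with the image, defined by
  trackable features (the foot contour template; the centroid of the
  silhouette reference points for tibia and femur);
* an *anatomical* frame CS_A defined by operator-clicked landmarks on
  the static reference image: lateral malleolus (LM), lateral femoral
  epicondyle (LE) and greater trochanter (GT). The tibia CS_A y-axis
  joins LM and LE; the femur's joins LE and GT; the foot CS_A x-axis is
  the line fit to the lower-posterior foot contour (the sole), oriented
  towards the toes; the pelvis CS_A x-axis is the line fit to the
  pelvis-marker upper contour around the lateral point PL.

The constant transform between CS_T and CS_A is computed once per
segment at calibration. During tracking only CS_T is re-registered each
frame; anatomical poses follow by composition, and each joint angle is
the signed difference of the adjoining anatomical-axis orientations,
offset so that the upright calibration posture reads zero everywhere
(this convention absorbs the 90-degree offset between the foot axis and
the shank axis). Flexion and dorsiflexion are positive.

The tibia template has ten reference points, the femur six: the
intersections of the silhouette contour with circles centred in the
proximal landmark whose radii are evenly spaced between 25% and 75% of
the segment length. This middle band avoids the joint-adjacent regions,
which deform most with soft tissue. We space the circles uniformly in
the band (the counts and the band are fixed; the spacing rule was an
open choice).

### Pelvis double calibration

The pelvis marker's shape changes through the cycle, so its lateral
point PL cannot be detected directly in every frame. Instead the
operator clicks PL on the first and last frames of each gait cycle; the
posterior point PP of the marker's upper contour *is* detectable
automatically. The horizontal distance d_x between PL and PP is
interpolated linearly over the cycle (`d_x(i) = d_x_first + Delta * i`,
`Delta = (d_x_last - d_x_first) / M`), and `PL_i = PP_i + (d_x(i), 0)`.
Pelvic tilt is the slope of the least-squares line through the upper
contour within ±20 px of PL.

## Per-frame tracking

Tracking is bottom-up: foot, then tibia, then femur; the pelvis is
independent of the leg chain.

**Foot.** An exhaustive grid search over rotations (0.5 deg step) about
the predicted LM and translations (±5 px) minimizes a contour
subtraction cost: template and observed contours are rasterized into a
common 1-px band raster and the cost is the pixel count of their
symmetric difference. The rotation span is ±10 deg about the predicted
rotation during stance and ±30 deg during swing; the spans are relative
to the velocity-extrapolated previous rotation (an absolute span would
clamp the foot at terminal stance, where it pitches well beyond 10 deg).
Ties are broken by the smallest displacement from the prediction, then
the smallest rotation offset. Two further choices matter in practice:

* the template is the *posterior half* of the calibrated foot-marker
  contour, and the observed contour is cut to the same *material*
  region along the candidate rotation's foot axis. Cutting at the image
  x-midpoint instead biases terminal-swing rotations by tens of degrees,
  because a pitched foot has a different apparent midpoint;
* a weak continuity prior (0.3 px of cost per degree of deviation from
  the predicted rotation) breaks near-flat cost minima; the heel-side
  contour alone constrains rotation poorly on a noisy boundary.

**Tibia and femur.** A registration of first approximation places the
segment by its proximal landmark (LM from the tracked foot; LE from the
tracked tibia) and rotates its calibrated axis onto the predicted distal
landmark direction. Around each predicted reference point a 10 × 10 px
region of interest is searched for the silhouette-contour point whose
distance to the proximal landmark best matches the calibrated circle
radius (tolerance 2.5 px); missing intersections — typically where the
contralateral leg occludes one side — are simply omitted. The remaining
correspondences are registered by the closed-form SVD (Kabsch) rigid
fit with the determinant forced to +1, followed by one refinement pass.
With fewer than two correspondences the first approximation is returned
and flagged degraded.

**Pelvis.** PP is detected as the most posterior point of the marker's
upper contour (per-column topmost pixels), PL follows from the double
calibration, and tilt from the line fit around PL.

### Robustness anchors

The hardest part of single-camera silhouette tracking is the overlap of
the two legs (and the two white socks) around each leg crossing. The
package treats observability honestly rather than forcing a fit:

* frames where the two sock blobs merge are *gaps*: the foreground foot
  is genuinely unobservable there. Gap frames are bridged by linear
  interpolation of the transform parameters between clean neighbours
  and flagged `merged_feet;interpolated`. (Matching against the merged
  contour was tried and reliably locked onto the flat stance foot.)
  The same rule feeds event detection: merged-frame centroids are
  interpolated;
* foot identities are maintained across a crossing by per-foot
  constant-velocity prediction that records only unmerged observations,
  so predictions coast through the merge at the last clean velocity;
* GT is a pelvis-fixed point, so the statically calibrated PL-to-GT
  offset, rotated by the measured tilt change, predicts GT at every
  frame from the tracked pelvis. Any femur fit whose orientation
  contradicts this anchor by more than 10 deg has locked onto the
  contralateral thigh and is replaced by the anchored registration
  (flagged `femur_anchored`);
* the knee prediction intersects circles of the calibrated tibia and
  femur lengths around the tracked LM and the anchored GT (taking the
  anterior solution: the knee does not hyperextend in gait); tibia fits
  with few correspondences are gated against this direction;
* foot LM velocity prediction is trusted only when built from two
  fresh, consecutive clean frames; otherwise the LM is re-anchored on
  the labelled blob centroid through the calibrated centroid-to-LM
  offset. After a crossing the search also widens (±75 deg, ±9 px) to
  re-acquire.

All interventions are flagged per frame in the output table.

## Events and spatiotemporal parameters

Heel strikes are the local maxima, and toe offs the local minima, of the
horizontal foot-pelvis centroid distance; extrema require a minimum
prominence (10 px) and a minimum separation (0.4 of the median event
spacing) to debounce boundary jitter, and plateaus resolve to their
first frame. Stride time is the frame difference between consecutive
ipsilateral heel strikes; stride length is the foot-centroid advance
converted through the calibrated scale; cadence assumes two steps per
stride; walking speed is their ratio.

## Curve processing and agreement statistics

Per-frame angles over a cycle are filtered with a zero-phase
fourth-order Butterworth low-pass at 10 Hz (forward-backward, odd
end-extension of 3 × order samples; the series is offset by its leading
sample so the zero initial state adds no step transient) and
time-normalized to 101 samples (0-100% of the cycle) by linear
interpolation. Agreement with a reference is quantified by RMSD, by MAE
and MAE% (the denominator is the mean reference value), and by the
linear-fit method: regressing the estimated curve on the reference
yields amplitude A0 (slope), offset A1 (intercept) and shape similarity
R² (computed directly from the residual and total sums of squares; it is
reported unclamped).

Zero-phase filtering was chosen because a causal filter's phase lag
would bias RMSD against any reference. Filtering before versus after
time normalization differ by under 0.5 deg RMS on smooth gait curves;
the pipeline filters first.

## The synthetic walker

`gait_spec()` / `generate_gait_trajectory()` / `simulate_trial()`
implement a ground-truthed articulated walker emulating the recording
protocol: 50 fps, homogeneous blue background, skin-toned body, white
pelvis blob and socks, the background leg phase-shifted by half a cycle
and occluded by the foreground leg (painter's order). Joint-angle
trajectories are truncated Fourier templates qualitatively matching
normal adult gait (hip about +30 to -8 deg, knee 4-60 deg, ankle -13 to
+12 deg, pelvic tilt of 2 deg amplitude at twice the stride frequency);
the exact coefficients are a fixture of the generator, not a
physiological claim. Speed presets covary speed and stride time (slow
0.93 m/s / 1.40 s, comfortable 1.25 / 1.20, fast 1.70 / 1.00). The foot
is a rigid flat-bottomed polygon so the sole line fit is well defined;
segment lengths default to thigh 410 mm, shank 400 mm, foot 240 mm,
pelvis depth 240 mm. True events are the interior extrema of the
continuous foot-pelvis centroid distance on a 20x oversampled time
grid, snapped to the nearest frame — which makes the event detector
exact on clean data by construction.

A 2D renderer cannot reproduce the parallax component of the pelvis
marker's apparent shape change; a small cyclic posterior-edge excursion
(2.5 mm amplitude) stands in for it, without claiming equivalence.
Optional acquisition noise comprises boundary-local pixel flips
(contour jitter), an illumination ramp, a hue-drift field and Gaussian
blur, all deterministic given the seed.

What passing on this generator shows — and what it does not: the
pipeline recovers the geometry it was designed for (rigid segments,
clean chroma separation, strictly sagittal motion, known garments). It
does not exercise cloth deformation, soft-tissue artefact, out-of-plane
rotation, shadows, or imperfect backgrounds; real-data performance is
bounded by those effects, not by the numbers reported here.

## Problem sizes, defaults and numerical choices

Validation trials are rendered at 1280 × 480 px, 3 mm/px, 50 fps, 1.5
gait cycles (one full ipsilateral stride plus margins), with 1 px
contour jitter; the default `gait_spec()` frame is the protocol's
1280 × 720. The static foot extent at 3 mm/px makes the recovered scale
exact to one part in eighty, which is why the scale measurement uses
the pixel-count extent (max - min + 1) of the marker and why the static
image alone receives a 3 × 3 morphological close/open cleanup before
calibration — single-pixel jitter protrusions otherwise bias the scale
by about 2%. Dynamic frames are never cleaned: closing can bridge the
two legs' silhouette contours exactly where the circle intersections
are sought.

Other defaults: HSV background tolerances ±10 deg hue, 0.25 saturation
and value; white filter S < 0.2, V > 0.8; minimum blob area 50 px²;
ROI half-size 5 px; intersection tolerance 2.5 px; rotation step
0.5 deg; all exposed through `trial_config()` / YAML.

Degenerate inputs are signalled with classed conditions
(`gait2d_no_subject`, `gait2d_no_markers`, `gait2d_no_events`,
`gait2d_calibration_failed`, ...) rather than silent defaults; ties in
"most posterior point" selection break towards the lowest y.

## Known limitations

Kinematics are available for the foreground limb only; bilateral output
requires walking both directions. Joint angles are planar projections
(foot transverse-plane motion is invisible, and the pelvis-anchored
femur gate inherits any pelvic-tilt estimation error, both of which cap
hip/ankle amplitude accuracy). The event detector assumes overground
walking with a roughly constant direction of progression. Anatomical
landmark clicks carry operator repeatability error that synthetic
trials, whose sidecar clicks are exact, do not model.
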