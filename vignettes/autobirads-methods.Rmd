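---
title: "Automated BI-RADS assessment of ultrasound sweep videos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated BI-RADS assessment of ultrasound sweep videos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autobirads)
```

## The problem

A breast ultrasound examination is acquired as a *sweep video*: the
transducer translates across the lesion at roughly constant speed, so the
imaged cross-section appears, grows to its mid-sweep maximum, shrinks and
disappears, with lesion-free frames at both ends. Radiologists describe
what they see with the six ACR BI-RADS lexicon categories — shape,
orientation, margin, echo pattern, posterior acoustic features,
calcification (fifteen levels in total) — and condense them into an
ordinal assessment category (here 2, 3, 4a, 4b, 4c, 5) that drives the
benign/malignant decision. The descriptors are well defined but their
application is subjective, and inter-reader variability is substantial.

This package implements that reading as an explicit, fully inspectable
computation: per-frame lesion segmentation, per-frame lexicon extraction by
morphological image processing, and a cross-frame score fusion that maps
frame-proportion evidence through a weighted rank-threshold table to a
category and a benign/malignant call. Every threshold is a named
configuration value, every decision is reported with the diagnostics that
drove it, and the whole pipeline is testable end to end against a built-in
speckle phantom generator with exact ground truth.

## The pipeline

### Segmentation

Breast lesions are hypoechoic against parenchyma, so the default runtime
engine is classical dark-object segmentation on each frame:

1. Gaussian smoothing (`smoothing_sigma`, default 2 px) to tame speckle.
2. A *robust background floor*: pixels below `median − 3·MAD` of the
   smoothed frame are seed candidates. We deliberately do not use Otsu's
   threshold as the default (it remains available as
   `threshold_method = "otsu_dark"`): on a frame whose lesion is small the
   histogram is effectively unimodal and Otsu's cut drifts into the
   background mode, flooding the dark speckle tail; on a two-level
   (heterogeneous) interior it splits *inside* the lesion. The robust
   floor, by contrast, is exceeded only by genuine dark structure.
3. Hysteresis growth: the seed component with the *darkest mean* (the
   lesion core — never the lighter posterior shadow) is grown at a
   permissive cut (`median − 2·MAD`), which recovers brighter lesion
   portions such as the near-isoechoic component of a mixed lesion or a
   blurred margin, followed by morphological open/close
   (`open_radius` 2 px, `close_radius` 3 px).
4. *Shadow trimming.* Posterior shadowing is as dark as the lesion, so the
   dark component can be the lesion plus a shadow column hanging below it.
   A lesion — even a spiculated one — tapers towards its bottom, while a
   shadow band keeps the full lesion width and ends abruptly wide. The
   row-width profile of a merged component therefore shows a
   dip-then-rise below the lesion equator. When that signature is present
   (dip below 85% of the equatorial width, followed by a ≥20% recovery,
   with an abruptly wide component bottom) the component is cut at the
   deepest dip. Shadow-free components never show the signature and are
   left untouched.
5. Hole filling (bright calcific foci punch holes into a dark mask), then
   two gates: `min_area` (64 px²) and `min_contrast` (background-minus-
   interior mean ≥ 0.08 on the smoothed frame). Absence is a value, not an
   error.

Across a video, a temporal pass drops isolated single-frame detections
flanked by absences. The engine is deliberately behind a narrow contract
(frames in, masks or absences out), so a learned network can replace it
without touching the rest of the pipeline; the attention and loss
operations such a network would use (`simam_weights`, `bce_loss`,
`focal_loss`, `ciou_loss`) are exposed as pure, unit-tested functions.

### Feature extraction

Each extractor maps (frame, mask) to one level with the diagnostics that
drove the call; all thresholds live in `feature_config()`.

* **Shape** — circularity `4πA/P²` (perimeter from the traced contour with
  Vossepoel–Smeulders step weights, which keep digital-perimeter error
  near 1%) and solidity (area over convex-hull area). Regular requires
  circularity ≥ 0.70 *and* solidity ≥ 0.90.
* **Orientation** — bounding-box extents along the image axes (rows are
  depth). Parallel ("wider than tall") wins ties, matching the clinical
  convention that only a clearly taller-than-wide lesion is suspicious.
* **Margin** — two diagnostics: *smoothness*, the raw contour perimeter
  over the perimeter of its 10-harmonic Fourier smoothing (spiculation and
  microlobulation inflate it; a smooth outline gives ≈ 1.0, and digital
  staircase effects stay below the 1.15 gate), and the *mean edge
  gradient*, the average absolute intensity step across the boundary
  normal over a ±2 px band of the despeckled frame. Circumscribed
  requires a smooth contour *and* a sharp edge (≥ 0.015 intensity/px). A
  Gaussian-blurred margin of σ = 8 px lands just below that gate — the
  gate was chosen so that the blur scale radiologists would call
  "indistinct" at this image scale fails it.
* **Echo pattern** — computed on the 3-px-eroded interior of the
  *despeckled* (σ = 2 px Gaussian) frame. Anechoic when the interior mean
  is ≤ 0.08; otherwise homogeneous when the coefficient of variation is
  ≤ 0.35, else heterogeneous. Despeckling matters: fully developed speckle
  at gamma shape 4 has CV = 0.5 on raw pixels, which would label *every*
  homogeneous lesion heterogeneous; smoothing suppresses speckle CV to
  ≈ 0.07 while leaving the structural CV of a genuine two-level interior
  (≈ 0.5) intact.
* **Posterior features** — the band directly beneath the lesion bounding
  box (height equal to the lesion height, same width) against same-depth
  flank bands of the same total width. Enhancement at a band/flank ratio
  ≥ 1.15, shadowing at ≤ 0.85.
* **Calcification** — the weak category, as any grayscale-threshold
  approach is on real data. The interior is eroded deeply (5 px): a
  segmentation mask overshoots the lesion by a few pixels and its closing
  can absorb bright inter-spicule tissue, and such rim pixels masquerade
  as foci, especially against a near-anechoic interior. Candidate pixels
  then exceed the robust interior level of a 7-px-radius white-top-hat by
  4 robust SDs (median + 4·MAD — robust so the foci themselves cannot
  inflate the cut); multiplicative speckle fragments a focus, so
  candidates are merged with a 1-px closing before components are sized.
  Foci under 2 px are discarded; ≥ 12 px is coarse; anything remaining is
  punctate. A known residual failure is structural: the stratum boundary
  inside a two-level heterogeneous interior rings in the top-hat and can
  register as a spurious (weight-0) coarse focus; this is why the
  recovery bar for calcification is 80% rather than 90%.

### Fusion

Features fluctuate across a sweep, so the per-frame labels are reduced to
per-category *frame proportions over lesion frames*, and a level is chosen
per category by inclusive thresholds: 0.5 for shape, orientation, margin,
echo and posterior; 0.2 for calcification (foci are transiently visible,
so even a minority of frames is evidence). Ties break toward the
higher-weighted (more suspicious) level. The chosen levels are scored:

| category | level weights |
|---|---|
| shape | regular 0, irregular 2 |
| orientation | parallel 0, not parallel 2 |
| margin | circumscribed 0, not circumscribed 2 |
| echo | anechoic −2, homogeneous 0, heterogeneous 1 |
| posterior | none 0, enhancement 0, shadowing 2 |
| calcification | none 0, coarse 0, punctate 2 |

and the total maps through rank thresholds ≤−1 → 2, 0 → 3, 1–2 → 4a,
3–4 → 4b, 5–6 → 4c, ≥7 → 5, with malignant at ≥ 4b. A simple-cyst
override (anechoic + circumscribed + regular + parallel, no calcification)
forces category 2. The published source of this design prints neither the
weights nor the rank thresholds; the table above is this package's own
construction, chosen so the canonical archetypes land correctly (simple
cyst → 2, all-benign solid → score 0 → 3, all-suspicious → score 11 → 5),
and every number lives in a user-editable `score_table()` (YAML-round-trip
via `save_run_config()`). The malignancy cut is likewise configurable and
documented as uncertain. When no frame contains a detectable lesion the
result is an explicit no-lesion report — deliberately distinct from
BI-RADS 1, which this model never emits.

## The phantom: what it emulates, and what a green test does not establish

`phantom_spec()` states a world: a lesion of known geometry swept by a
linear transducer. Radii scale as `sqrt(max(0, 1 − ((t − t_mid)/t_half)²))`
with `t_half = 0.4 · n_frames` — an ellipsoid traversed at constant speed,
the simplest physically motivated reading of the acquisition protocol —
so the first and last frames are lesion-free. The scene is composed
(background 0.5; interior pattern; optional spiculation by radial cosine
perturbation; optional Gaussian margin blur; a posterior band of height
equal to the vertical radius multiplied by the posterior gain; calcific
foci painted at intensity 0.95) and then multiplied by unit-mean gamma
speckle (shape 4, the regime of fully developed speckle after log
compression; CV = 0.5). Masks are a deterministic function of the
geometry alone — the seed only moves the speckle.

Defaults worth stating because tests depend on them: 128×128 frames,
24 frames per sweep, mid-sweep radii (16, 26) px, interior 0.30
(homogeneous), 0.02 (anechoic: essentially echo-free), 0.22
(heterogeneous, split at ±0.15 into 0.07/0.37 — both components kept
hypoechoic relative to parenchyma, as real mixed cystic-solid lesions
are; a +0.15 component brighter than background would make half the
lesion sonographically invisible, which is a different lesion, not a
harder test). Posterior gains 1.5/0.5. Spiculation (12, 6 px): twelve
lobes put the contour's frequency content just above the 10-harmonic
margin smoother, so a spiculated-but-sharp margin is flagged by shape
*and* margin, as it should be. The malignant archetype uses a deeper
image (160 rows) so that the posterior band below its tall outline stays
inside the frame, and a darker interior (0.18) because its blurred margin
mixes background into the interior and would otherwise wash out the
two-level echo contrast.

The phantom does **not** emulate: attenuation with depth, beam-width and
focal-zone effects, refraction and reverberation artifacts, anatomical
clutter (ducts, ribs, Cooper ligaments), hyperechoic envelopes around
lesions, or operator motion jitter. A green recovery battery therefore
establishes that the operators implement their stated definitions and are
robust to fully developed speckle at the stated contrasts — not that the
pipeline reaches clinical accuracy on hospital data. The published
clinical numbers (AUC 0.87, kappa 0.82/0.60) require the original 292
clinical videos and trained networks and are out of scope by design; only
their statistical machinery is reproduced and oracle-tested here.

## Statistics

`evalstats` reproduces the arithmetic of a reader-study analysis:
confusion-matrix metrics with integer-percent reporting (half away from
zero); tie-aware ordinal AUC (Mann–Whitney with half credit) with DeLong
structural-component variance, normal CIs truncated to [0, 1], and the
paired DeLong test via component covariances; Cohen's kappa with the
conventional interpretation bins (0.4–0.59 weak, 0.6–0.79 moderate,
0.8–0.9 strong, >0.9 perfect); McNemar's test (exact two-sided binomial
below 25 discordant pairs, continuity-corrected chi-square above — the
two branches agree within 0.02 in p at the boundary for balanced counts);
and percent/conditional agreement. The AUC implementation is
property-tested against brute-force pair enumeration up to n = 200.

One reporting subtlety is documented rather than resolved: among the
published confusion cells, one (116/124 printed as 93%) is inconsistent
with the rounding that reproduces all the others (93.548% rounds to 94).
The package rounds half away from zero and the acceptance test keeps the
published cell as a faithful, knowingly failing assertion.

## Numerical choices and degenerate inputs

* Images are numeric matrices in [0, 1], (row, col), 1-based, row 1 at the
  skin; mask bounding boxes are 1-based closed intervals (idiomatic R),
  while `ciou_loss` boxes are continuous half-open, matching its worked
  example. `sweep_radius` frame indices are 0-based.
* Two empty masks compare as Dice = IoU = 1 (needed for blank-frame
  regression tests); probabilities at 0/1 are clamped to [1e−7, 1−1e−7]
  with a note; kappa bin edges are guarded against floating-point noise;
  an empty interior after erosion falls back to a lighter erosion; a
  posterior band that does not fit in the frame degrades to "none" with a
  warning rather than failing the whole frame.
* All randomness flows from explicit seeds; per-frame speckle streams are
  derived from the spec seed, so a re-render of any single frame is
  bit-identical.

## Known limitations

* The classical engine assumes hypoechoic lesions; hyperechoic lesions
  need `threshold_method = "fixed"` with bright polarity, and the shadow
  trim assumes approximate vertical symmetry of the lesion outline.
* Calcification detection inherits the weaknesses the original clinical
  study reports for its own algorithm: foci are found by grayscale
  exceedance, so subtle foci and echogenic envelopes confound it; the
  recovery bar is correspondingly lower (80%).
* Video containers (AVI/MP4) are not read in this build — no codec is
  available in the supported toolchain; cine loops are exchanged as
  directories of zero-padded PNG frames.
* BI-RADS 1 and 6 are out of scope; the model reports "no lesion"
  explicitly instead of category 1.
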