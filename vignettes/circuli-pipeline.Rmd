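---
title: "Methods: automated circuli detection along radial scale transects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated circuli detection along radial scale transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circulus)
```

## The problem and the model

A scale impression images the calcified growth ridges (circuli) of a teleost
scale as dark, roughly concentric bands on a bright background, radiating
from the dark first-formed centre (the focus). Growth analysis needs the
ordered distances of circuli from the focus along one or more radial
transects, and their first differences (spacings). The package treats both
stages as object detection in pixel coordinates:

* the **focus** is one axis-aligned bounding box on the whole image;
* each **circulus** is one box on a transect strip, whose x-centre is the
  circulus' distance from the focus in pixels.

The pipeline makes three structural assumptions: the focus is a compact dark
blob (scales with damaged or incomplete centres must be excluded upstream);
circuli cross a radial strip as approximately straight dark bands, so a
strip's column-mean intensity profile carries their signal; and all outputs
are wanted on the scale of the original image, so every detector works
through exact coordinate mappings back to full resolution.

## Coordinate and geometry conventions

All pixel coordinates are 0-based and continuous, origin at the top-left,
x rightwards, y downwards. Angles are degrees counter-clockwise from +x, so
90° points to the image top; the default fan 0/45/90/135/180 sweeps the
upper half of the scale, which is how impressions are conventionally framed
(longest radial axis vertical). Transects are single rays from the focus-box
centre outward, not diameters: the freshwater zone simply begins a few
columns from the origin. Strip sampling uses bilinear interpolation at 1 px
steps along and across the ray; the across-ray offset of row *r* (0-based)
is `r − (width−1)/2` times the +90° unit normal. The strip width rule —
`floor(min(focus-box edge)/2)`, identical for all angles of one scale — and
the length rule — the largest number of columns strictly interior to the
image — are fixed by worked examples in the test suite.

## Reference detectors

Production use plugs trained convolutional detectors in through
`detector_backend()` (raster in, scored boxes out; pure in its
configuration). The package ships classical reference implementations so the
whole pipeline runs and is testable without trained weights. They are honest
classical detectors, not emulations of a network.

**Focus** (`reference_focus_detector`): Gaussian smoothing (σ 1.5 px), dark
thresholding at an intensity quantile (default 0.15 %, plus a 10⁻⁶ whisker
so flat plateaus stay whole), morphological opening (radius 2 px) to remove
thin band fragments, connected components filtered to a plausible area range.
Because the quantile mask keeps only a blob's darkest core, each candidate
box is grown to the blob's extent at an intensity a quarter of the way from
the core back to the median background. Score = relative core darkness ×
centrality; ties break to the larger component, then the upper box. Images
in which nothing is meaningfully darker than the median (e.g. blank frames)
yield no candidates, and `detect_focus()` then signals `focus_not_found` —
such scales are skipped, never guessed. For speed the backend sees a copy
downscaled to ≤ 1376 px on the long side (the working input geometry of the
trained focus stage); boxes are mapped back to original pixels.

**Circuli** (`reference_circuli_detector`): the strip's column-mean profile
is Gaussian-smoothed (σ 2 px), inverted (bands are dark), and local maxima
with prominence ≥ 0.05 intensity units become detections; peaks closer than
3 px collapse to the most prominent. Box width is the peak's width at half
prominence, **capped at half the distance to each adjacent surviving peak**
and floored at 3 px; height is the full strip. The cap matters: inside the
narrowly spaced freshwater zone the locally tallest peak otherwise measures
its prominence against the marine-zone baseline and its half-prominence
width spans the whole zone, which cannot match a ground-truth band at
IOU 0.5. Scores are `min(1, prominence / 0.15)`: weak, crowded freshwater
bands score ~0.4–0.7 while clean marine bands saturate at 1, reproducing the
qualitative confidence-versus-distance pattern expected of any detector on
this material. The 0.15 calibration keeps freshwater peaks above the fixed
0.3 acceptance threshold of the circuli stage; it is a property of the
reference detector, not of the evaluation.

After any backend, `detect_circuli()` applies the stage score threshold
(default 0.3) and greedy non-maximum suppression at IOU 0.5 (matching the
evaluation threshold, since no separate value is prescribed), then sorts by
centre column.

## Evaluation protocol

`match_detections()` processes detections in descending score order (ties:
input order) and pairs each with the unmatched ground truth of highest IOU
provided IOU ≥ 0.5 (inclusive). Precision, recall and F1 follow; a zero
denominator yields `NA`, which propagates and is omitted from means — never
coerced to 0 or 1. AP uses all-point interpolation (monotone precision
envelope, exact step area). MCE averages centre distances over matched pairs
only: unmatched boxes already appear as FP/FN, and including them would
double-count. `evaluate_dataset()` reports pooled metrics (counts summed
before ratios, AP on the pooled ranking) *and* unweighted per-transect macro
summaries (mean, median, 5th/95th percentiles): the two answer different
questions and differ whenever transects vary in length, so both are
labelled. Note that greedy score-ordered matching is not exactly symmetric
under swapping the two box sets when overlap chains occur; for realistic
two-labeller data (the same objects marked with small independent jitter)
the swap exactly exchanges FP with FN and precision with recall.

## The synthetic scale simulator

`render_scale()` draws a bright noisy background, a dark focus disc, and one
dark Gaussian-cross-section band per ring along ellipses with vertical major
axis (minor radius = major × (1 − eccentricity)). Ring radii come from
`generate_ring_radii()`: a constant-spacing freshwater zone, then marine
spacings `base + A·sin(2πi/period)`, all with seeded multiplicative jitter.
Ground truth is exact: the focus box from the disc geometry, and per-angle
circuli boxes at the closed-form ray–ellipse intersection distances
(verified against a bisection root-find in the tests). The focus disc is
drawn 1.5× deeper than the bands, as the dense first-formed material of a
real focus images darker than single circuli. Rings may be locally erased
over a random angular segment (`breakage_prob`), emulating broken bands;
ground truth still lists such rings, so breakage costs the detector recall,
as it would a human.

Default parameters describe one realistic operating point, chosen once:
768 px image, 12 px focus radius, 12 freshwater rings at 8 px, 18 marine
rings at 12 ± 3 px over an 8-ring season, band σ 1 px, contrast 0.45, noise
σ 0.03, eccentricity 0.12, 5 % jitter, 5 % breakage. Two constraints shaped
them. First, validity: every spacing must exceed 2 × band σ or adjacent
bands are unresolvable *by construction* (enforced by a validator). Second,
detectability for the profile detector: two bands of cross-section σ_b
blur to σ_eff = sqrt(σ_b² + σ_smooth²) in the smoothed profile, and their
dips merge below a separation of roughly 2·σ_eff ≈ 4.5 px; the worst-case
effective freshwater spacing — compressed by eccentricity along horizontal
transects and shrunk by jitter, 8 × 0.88 × 0.95 ≈ 6.7 px — stays above it.
A trained 2-D detector would not share this exact limit, but any detector
has one in the freshwater zone, which is precisely where real confidence
degrades.

What the simulator does **not** emulate: debris and impression defects,
damaged or off-centre foci, band cut-overs, illumination gradients, texture
within bands. Passing the synthetic end-to-end tests therefore shows the
pipeline's geometry, bookkeeping and reference detectors are correct under
the stated image model — not that the reference detectors would match a
trained network on real archive material.

## Numerical choices and edge cases

* Split rounding: half-up on train and validation counts, remainder to test
  — the only convention reproducing 725/207/103 from 1035 at 70:20:10. The
  split is simple random, not stratified by age class; stratification is the
  caller's job if needed.
* Out-of-bounds annotation boxes clamp with a warning (real files overshoot
  slightly); degenerate boxes are errors everywhere.
* Score thresholds are inclusive (≥): they are the *minimum* score required
  when accepting a detection.
* Duplicate circuli centres (within 10⁻⁹ px) collapse with a warning; fewer
  than two distances yield an empty spacing vector with a warning, not an
  error — short transects are data, not bugs.
* Normalization divides distances by the per-transect maximum (so profiles
  share a (0, 1] axis); spacings stay in pixels, with optional
  max-normalization off by default. Spacings are attributed to the midpoint
  of their bounding circuli for plotting and aggregation.
* `aggregate_transects()` linearly interpolates each profile onto a common
  grid and takes pointwise means and quantiles; it is a deliberately simple
  substitute for hierarchical smoothing models, which belong downstream.
* Constant images rescale to all zeros with a warning; per-image pipeline
  failures are isolated and reported as skipped results, never fatal to a
  batch; identical inputs and configuration give bit-identical outputs.

## Problem sizes in the test suite

The suite exercises 20 full-size (768 px, 30-ring) scales across 5 angles in
the end-to-end recovery test, plus ~20 compact (320 px, 13–14-ring) scales
in module tests; oracle equivalence runs 100 random box pairs (IOU), 100
random rankings (AP) and all detection/ground-truth set sizes up to 4×4
(matching). These sizes give stable statistics (≈3000 circuli end-to-end)
while keeping the default suite around a minute.

## Known limitations

The reference focus detector assumes a reasonably centred, well-framed
scale; the circuli detector is 1-D and cannot exploit band continuity across
strip rows; CNN training is out of scope by design (the backend contract and
`training_config()` specify exactly what a trained model must provide); and
evaluation inherits the usual caveat that ground truth from a single
labeller is itself ambiguous — the two-labeller comparison mode exists
precisely to quantify that.
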