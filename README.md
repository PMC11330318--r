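# circulus

Automated extraction of growth-increment data from images of teleost fish
scales.

Fish scales record somatic growth as concentric calcified ridges (circuli)
radiating from the scale's first-formed centre (the focus). The distances
between successive circuli along a radial transect are a longitudinal growth
record — narrow spacings in the freshwater (juvenile) zone of a salmon
scale, wider and seasonally modulated spacings in the marine zone — and are
the raw material of sclerochronological growth analyses. Demarcating
hundreds of circuli by hand is the bottleneck: this package implements the
fully automated, two-stage detection pipeline for that task, together with
the complete evaluation protocol used to judge such detectors and a
synthetic scale-image simulator with pixel-exact ground truth so the whole
system is testable without microscope images or trained network weights.

The pipeline (per image):

1. **Preprocess** — grayscale conversion and intensity rescaling to [0, 1].
2. **Focus detection** — a single bounding box around the scale focus
   (pluggable detector backend; a classical blob detector is included).
3. **Transect extraction** — radial strips at configurable angles (default
   0, 45, 90, 135, 180 degrees), pivoting at the focus-box centre, each of
   width `floor(min(focus-box edge)/2)` and running to the image edge, with
   exact bidirectional strip-to-image coordinate mapping.
4. **Circuli detection** — one bounding box per circulus along each strip
   (pluggable backend; a 1-D profile-prominence detector is included),
   score-thresholded (default 0.3) and non-maximum suppressed.
5. **Spacings** — ordered centre distances from the focus and their first
   differences, plus normalized profiles and multi-transect aggregates.

Detector quality is measured exactly as in the object-detection literature:
a detection is correct when IOU ≥ 0.5 with an unmatched ground-truth box
(greedy matching in descending score order), precision = TP/(TP+FP),
recall = TP/(TP+FN), F1 their harmonic mean, AP the area under the
all-point-interpolated precision–recall curve, MCE the mean Euclidean
distance between matched box centres, and the signed percentage difference
in circuli counts per transect. Pooled (count-summed) and macro
(per-transect averaged) summaries are both reported and labelled.

Externally trained convolutional detectors (the intended production
backends) plug in through a one-function contract — raster in, scored boxes
out — and `training_config()` records the training geometry the two stages
assume (1376×1376 focus inputs, 64×3904 transect strips, score thresholds
0.5/0.3).

## Worked example

```r
library(circulus)

p  <- scale_sim_params(seed = 42)      # simulator defaults: 768 px image,
sc <- render_scale(p)                  # 12 freshwater + 18 marine rings
res <- process_scale(sc$image, pipeline_config(), image_id = "demo")
res
#> <scale_result> demo: focus (384.5, 384.5), 5 transect(s), 152 circuli

res$series[["90"]]$spacings[1:10]
#> [1] 8 8 8 8 8 8 8 8 8 8     # the simulated freshwater spacing, recovered

gt <- ground_truth_for_transect(sc, 90, res$width)
evaluate_transect(res$detections[["90"]], gt)
#> <transect_eval> TP 30 FP 0 FN 0 | P 1.000 R 1.000 F1 1.000 | MCE 0.41 px
```

All 30 simulated rings on the vertical transect are recovered with a mean
centre error of 0.41 px; the focus centre is found at (384.5, 384.5) against
a simulated centre of (384, 384). `pipeline_spacings()` flattens a batch of
results into a tidy one-row-per-spacing table ready for CSV export, and
`diagnostics()` writes per-transect score-versus-distance tables and overlay
images (detections in red, ground truth in green).

A thin command-line front end ships in `inst/cli/circulus`:

```sh
Rscript inst/cli/circulus simulate --out sim --n 5 --seed 1
Rscript inst/cli/circulus run --images "sim/*.png" --out out --diagnostics
Rscript inst/cli/circulus evaluate --detections out --ground-truth sim \
    --out eval.json
```

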