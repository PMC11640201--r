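# spiralpd

Screening for Parkinson's disease (PD) from plain raster images of
hand-drawn Archimedean spirals. The package is aimed at researchers and
tool-builders who want a tablet-free spiral test: everything is computed
from a scanned or photographed pencil-and-paper drawing — no pen
trajectories, timings, or pressure channels are required.

## Method

A guided Archimedean spiral follows *r = aθ*. A drawing is processed as:

1. **Binarize** — Gaussian blur + Gaussian-weighted adaptive threshold
   (dark strokes on light paper).
2. **Thin** — Zhang–Suen morphological thinning to a one-pixel skeleton.
3. **Unwrap** — walk the skeleton from the centre outward; each pixel *i*
   contributes the distance *dᵢ = √((xᵢ−x_c)² + (yᵢ−y_c)²)* and a
   phase-unwrapped polar angle, turning the 2-D drawing into a 1-D
   angle–distance trace. The centre starts at the largest contour's area
   centroid and is refined by harmonic regression (a centre offset shows up
   as a once-per-revolution wobble in the distances). Self-intersecting
   drawings are rejected as *unusable*.
4. **Tremor signal** — a cubic smoothing spline with residual budget
   *s = n·N* (default *N = 10*) is the idealized, tremor-free path; the
   deviation (trace − spline) is treated as a time series sampled at
   *f_s = n/10 s* Hz.
5. **Features** — from the length-normalized, single-sided FFT spectrum:
   peak magnitude, peak frequency, SNR, variance and bandwidth, using a
   noise threshold of twice the mean magnitude (3-decimal rounded), with
   `SNR = (Σs²/|s|)/(Σn²/|n|) − 1` over signal/noise bins. From the
   grayscale image: pencil **pressure** (mean stroke intensity below the
   refined threshold `2·mean − 255`) and **thickness** (stroke pixels per
   unit boundary arc length).

Feature tables (`F` frequency, `P` pencil, `FP` both) feed grid-searched
classifiers (decision tree, random forest, SVM, XGBoost, AdaBoost) with
stratified 5-fold cross-validation and fold-wise z-score normalization.
Metrics are the usual confusion-matrix quantities (positive class
*parkinson*; headline precision/recall are support-weighted averages).

A seeded synthetic spiral generator renders the study conditions (4.5
revolutions, 75 mm guide radius, clockwise, ~10 s drawing time) with a
controllable radial tremor *r(θ) = aθ + A·sin(2πf·t)*, so every pipeline
stage can be validated against known ground truth.

## Worked example

```r
library(spiralpd)

# a synthetic Parkinsonian drawing: 5 px tremor at 5 Hz
spec <- spiral_spec(a = 75 * 2 / (2 * pi * 4.5),
                    tremor_amplitude = 5, tremor_frequency = 5, seed = 42)
img <- render_spiral(spec)
an <- analyze_spiral(img)
an
#> Spiral tremor analysis
#>   trace: 2744 points, fs = 274.4 Hz
#>   deviation RMS: 3.162 px
#>   peak 1.8899 px at 5.00 Hz | SNR 1668.82 | variance 0.07065 | bandwidth 58 bins
```

The spectral peak sits exactly at the injected 5 Hz tremor, with a large
SNR; a tremor-free drawing instead gives a deviation RMS around 0.3 px and
an SNR near 5. End-to-end classification on a labeled synthetic cohort:

```r
set <- make_labeled_set(30, 30, spiral_ranges("healthy", 2),
                        spiral_ranges("parkinson", 2), seed = 7)
tab <- clean_table(build_feature_table(set, feature_set = "FP"))
parts <- split_table(tab, 0.2, seed = 1)
model <- train_grid_search(parts$train, "rf", seed = 1)
evaluate(model, parts$test)
#> Evaluation: RF on FP features, 12 test rows
#>   accuracy 100.00% | weighted precision 100.00% | weighted recall 100.00% | F1 100.00%
#>   confusion matrix (truth x predicted):
#>            predicted
#> truth       healthy parkinson
#>   healthy         6         0
#>   parkinson       0         6
```

Single drawings are classified with `predict_image(model, "drawing.png")`,
which returns `"healthy"`, `"parkinson"`, or `"unusable"` for drawings whose
features cannot be computed. A command-line interface covering simulation,
feature extraction, training, evaluation and prediction ships in
`inst/cli/spiralpd.R`.

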