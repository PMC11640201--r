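---
title: "Tremor analysis of hand-drawn Archimedean spirals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tremor analysis of hand-drawn Archimedean spirals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralpd)
```

## The problem

Parkinson's disease (PD) produces motor signs — rest/action tremor,
bradykinesia, rigidity — that are visible in how a person draws a guided
Archimedean spiral. Clinics use spiral drawing as a cheap screening test, but
most automated analyses require a graphics tablet that records pen position
and pressure over time. `spiralpd` works from a plain raster image of a
pencil-and-paper drawing: it converts the drawing into a one-dimensional
tremor signal, summarises that signal in the frequency domain, adds two
intensity-based pencil features, and classifies the drawing as healthy or
Parkinsonian.

## The model

A guided Archimedean spiral follows $r = a\theta$ in polar coordinates: the
radius grows linearly with the turning angle, at rate $a$ (px/radian). A
drawing is processed in five stages.

1. **Binarization.** The grayscale image is smoothed with a small Gaussian
   filter and adaptively thresholded: a pixel is stroke if it is darker than
   its Gaussian-weighted local mean minus an offset. Defaults: 5 px blur
   kernel, 11 px threshold block, offset 2 — the usual defaults for this
   operator family; all exposed as arguments. The polarity is fixed
   dark-on-light; inverted scans are not supported.

2. **Thinning.** The stroke mask is reduced to a one-pixel skeleton with the
   two-subcycle Zhang–Suen scheme, iterated to a fixed point (hence
   idempotent). Thinning only removes pixels, so the skeleton is a subset of
   the mask.

3. **Unwrapping.** The largest contour's area centroid seeds the spiral
   centre. The skeleton path is walked from the pixel nearest the centre
   outward over 8-neighbours; each pixel contributes its Euclidean distance
   to the centre and its polar angle, cumulatively phase-unwrapped so the
   angle is continuous and increasing across revolutions. Pixels whose
   Rutovitz crossing number is 3 or more are branch points: they arise from
   self-intersecting drawings, and such drawings are rejected as *unusable*
   rather than repaired, mirroring the exclusion protocol used for real
   drawings. A raw neighbour count is deliberately **not** used as the
   junction test — ordinary staircase corners of a digital curve have three
   8-neighbours and are perfectly traversable.

   The area centroid of a spiral ribbon is systematically offset from the
   true spiral centre by a distance of order $a$ (the outermost, incomplete
   turn pulls it sideways). An offset centre contaminates the unwrapped
   distances with a once-per-revolution sinusoid that would dominate the
   tremor signal, so the pipeline refines the centre by harmonic regression:
   regressing distances on the angle and on the direction cosines
   $(\cos\phi_i, \sin\phi_i)$ recovers the offset exactly (to first order),
   and one or two refinement passes cancel the wobble.

4. **Line of best fit and tremor signal.** Distance as a function of
   unwrapped angle is fitted by a cubic smoothing spline whose residual sum
   of squares is driven to the budget $s = n \times N$, with $n$ the number
   of trace points and $N = 10$ by default ($N$ trades off how much drawing
   drift the "ideal" curve absorbs; $N = 0$ interpolates, large $N$
   approaches the least-squares line, which for an Archimedean spiral is the
   ideal profile). The tremor deviation is the pointwise difference between
   the trace and this idealized curve. Trace points are treated as uniformly
   spaced over a nominal 10 s drawing time, giving a synthetic sampling rate
   $f_s = n / 10$ Hz.

5. **Features.** The deviation signal's FFT magnitudes are divided by $n$
   and the first $\lfloor n/2 \rfloor$ bins retained (single-sided, not
   doubled; the DC bin is kept and takes part in the peak search). Five
   frequency features are computed: peak magnitude, peak frequency (lowest
   index on ties), signal-to-noise ratio, variance, and bandwidth. The noise
   threshold is twice the mean magnitude, rounded to three decimals; bins
   strictly above it are signal, the rest noise, and
   $$\mathrm{SNR} = \frac{\sum s_i^2/|s|}{\sum n_i^2/|n|} - 1 .$$
   Variance is the population variance of the signal bins (zero for a single
   bin, `NaN` for none, in which case the SNR is `NaN` too and the row is
   later dropped); bandwidth is the count of signal bins. Two pencil
   features come from the grayscale image directly: the stroke mask is all
   pixels strictly below the refined threshold $2\,\overline{I} - 255$
   (clamped to $[0, 255]$), pressure is the mean stroke intensity, and
   thickness is the stroke pixel count divided by the total boundary arc
   length of the mask (outer plus hole boundaries; because a ribbon has two
   sides this is a consistent relative measure, roughly half the geometric
   width).

## Classification

Feature tables (sets `F` = 5 frequency features, `P` = 2 pencil features,
`FP` = all 7) are cleaned of rows with undefined values and classified with
five grid-searched families: decision tree (rpart), random forest (ranger),
SVM (e1071), XGBoost, and AdaBoost over depth-1 stumps (implemented in the
package). Grid search uses stratified five-fold cross-validation in which
each fold's z-score scaler is fitted on that fold's training portion only
and applied to its validation portion — perturbing validation rows provably
never changes a training fold's scaler. The best mean-CV-accuracy grid point
(first on ties) is refitted on all training rows. Metrics follow the
standard confusion-matrix definitions with *parkinson* as the positive
class; headline precision/recall are support-weighted class averages, and
percentages are rounded to two decimals. A gradient-boosting family with
ordered target statistics (CatBoost) is used in some comparable studies but
has no R implementation available here; XGBoost covers the
gradient-boosting family.

## The synthetic generator

`spiral_spec()` / `render_spiral()` / `make_labeled_set()` emulate the study
conditions for guided drawings: 4.5 revolutions, 75 mm maximum radius
(mapped at a configurable 4 px/mm by default), drawn clockwise over a
nominal 10 s. Tremor is an additive radial sinusoid
$r(\theta) = a\theta + A \sin(2\pi f t(\theta) + \phi)$ with the time $t$
advancing uniformly along the arc length, so a rendered spiral carries
exactly $f \times 10$ tremor cycles and the ground-truth frequency is
unambiguous. Strokes are stamped as hard-edged disks (no anti-aliasing, so
threshold behaviour is predictable) with per-pixel Gaussian intensity
jitter. The innermost half radian of the guide is skipped so the stroke
never self-overlaps where the curvature radius falls below the stroke
half-width. Healthy cohorts use sub-pixel tremor amplitudes and dark, firm
strokes; Parkinsonian cohorts use 3–8 px amplitudes in the classical 4–6 Hz
parkinsonian band and lighter strokes (reduced pen pressure). The frequency
band is a literature convention: the source dataset does not state one.

The generator does **not** emulate pen lifts, in-air strokes, micrographia
progression, hesitation marks, drawing-speed variation (the 10 s duration is
nominal and shared), paper texture, or scanner artifacts. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers known
ground truth and orders feature sets sensibly — not that the reported
real-data accuracy transfers to new clinical images.

## Numerical choices and degenerate inputs

* "Exceeds the threshold" is strict (`>`) everywhere; a tie counts as noise.
* The smoothing spline's $\lambda$ is root-solved on a log grid so the
  residual sum of squares meets the budget; when even the maximally smoothed
  fit (the least-squares line) sits within the budget, the line is used.
  When the tremor residual exceeds the budget ($A \gtrsim \sqrt{2N}$ px) the
  spline starts absorbing tremor, capping the deviation RMS near
  $\sqrt{N}$ px: SNR therefore rises steeply with amplitude until roughly
  4–5 px and then saturates — seed-averaged SNR is reliably increasing over
  0/2/4 px but the 4→8 px step can be flat.
* A rasterized skeleton quantizes distances to ~0.3 px RMS of broadband
  noise. A tremor-free drawing consequently has a *flat* deviation spectrum
  in which about 4–6 % of bins always exceed twice the mean: the bandwidth
  feature of a clean drawing is tens of bins (scaling with trace length),
  not a handful. Only the continuum limit (deviation identically zero)
  gives an empty signal set. Bandwidth separates tremor-free from tremulous
  drawings by *relative* size, in combination with SNR and peak magnitude.
* Unusable drawings (junctions, blank pages, empty masks) yield `NaN`
  feature rows, removed by `clean_table()`; `predict_image()` reports
  `"unusable"` rather than guessing.
* Rotation augmentation (−45° to 165° in 15° steps) uses bilinear
  resampling with white fill; the 0° copy is bit-identical to the input.
  Augmentation is intended for training data only — evaluating on rotated
  copies of training images would leak.
* Tests and the acceptance script render at 2 px/mm (≈330 px canvases,
  ~2,500-point traces), a problem size chosen once for the whole suite;
  the package default stays 4 px/mm.

## Limitations

* The centre refinement assumes a mostly monotone spiral; heavily distorted
  drawings fall back to the unrefined centroid behaviour and typically end
  up excluded as unusable.
* Thickness is relative (pixels per boundary length), not a calibrated
  width in millimetres; compare it only across images scanned at the same
  resolution.
* Real-data performance claims cannot be validated without the original
  drawings; the packaged CLI (`inst/cli/spiralpd.R`) runs the full
  extraction/training/evaluation protocol should a licensed copy of the
  dataset be available.
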