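---
title: "Classifying DESI-MSI pixels with the multinomial lasso: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying DESI-MSI pixels with the multinomial lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Desorption electrospray ionization mass spectrometry imaging (DESI-MSI)
rasters a tissue section at ~200 µm resolution and records one negative
ion mode mass spectrum per pixel, dominated by free fatty acids (m/z
200–400) and glycerophospholipids (m/z 700–1000). Pancreatic surgical
margins pose a three-class problem: pancreatic cancer, normal pancreatic
glands, and normal stroma have distinguishable lipid profiles — glands
rich in oleic (m/z 281.2), palmitic (m/z 255.3) and arachidonic (m/z
303.3) acid and their dimers (m/z 537.0, 563.0); cancer enriched in
polyunsaturated fatty acids (m/z 303.3, 331.2) and in PC/PG/PI species
(m/z 792.4, 794.4, 773.6, 885.6); stroma showing a markedly lower total
ion count with PS species (m/z 788.8, 816.5). `desilasso` classifies
each pixel into one of these classes, evaluates the classification
against pathology, and rolls pixel calls up to sample- and margin-level
verdicts.

## Model

### Features

Spectra arrive on a 13,320-channel axis spanning m/z 90–1,200 (0.0833
m/z per channel). `bin_features()` averages non-overlapping blocks of
six channels, giving 2,220 features about 0.5 m/z wide, each labeled by
its channels' mean m/z (displayed to one decimal). Binning is the only
spectral preprocessing: it reduces dimensionality and absorbs small
registration differences between spectra, so no smoothing or peak
alignment is applied on top. A trailing partial bin, when the channel
count is not a multiple of the bin size, averages over its actual
members. Intensities are used raw by default; `normalize_tic()` offers
per-pixel total-ion-current scaling for users who want robustness to
acquisition drift, at the price of discarding the total-abundance
contrast that itself separates stroma from the other classes. Whether
to normalize is genuinely open — the classifier standardizes features
internally either way — and the package defaults to raw intensities
with the option exposed.

### Classifier

`fit_multinomial_lasso()` minimizes

$$\frac{1}{n}\sum_{i=1}^n -\log P(y_i \mid x_i; b, W) \;+\;
\lambda \sum_{j,k} |w_{jk}|,
\qquad P(y=k\mid x) = \frac{e^{b_k + x^\top w_k}}{\sum_l e^{b_l + x^\top w_l}}$$

over features standardized to zero mean and unit (population) variance.
Weights are reported on that standardized scale: dimensionless,
comparable across m/z, with the standardization stored so users can map
back. A positive weight marks an ion whose abundance characterizes a
class; a negative weight, an ion whose low abundance or absence does.
The penalty is plain, unweighted L1 across all features and classes.

The solver is cyclic coordinate descent: per class, the softmax
likelihood is majorized by a weighted least-squares problem (IRLS
weights $p(1-p)$, floored at $10^{-5}$ — the floor cancels from the
fixed-point condition, so it does not bias solutions), solved over an
active feature set; a full-gradient Karush–Kuhn–Tucker (KKT) screen
grows the active set until no coordinate violates stationarity. Paths
are warm-started from larger penalties, with a sequential strong rule
pre-activating likely violators. Numerical contract: relative
objective-change tolerance 1e-7, KKT tolerance 1e-6 (both exposed);
the softmax over-parametrization is harmless because the L1 penalty
picks a distinguished representative and the objective value is unique.
`lambda_max`, computed from the null-model gradient, is the smallest
penalty with an all-zero weight matrix; the path default is 100
log-spaced values down to `lambda_max * 1e-4`.

Exact probability ties in prediction go to the first class in the fixed
order cancer < glands < stroma; ties in penalty selection go to the
larger (sparser) penalty. Both choices exist purely for determinism.

### Penalty selection

`cv_select_lambda()` runs leave-one-patient-out cross-validation: folds
are patients, never random pixel subsets, because adjacent pixels of one
patient are heavily correlated and pixel-random splits leak patient
identity into the held-out score. The chosen penalty minimizes total
misclassified held-out pixels (a per-patient-mean alternative is
exposed via `weighting = "patient"`, since either reading of "fewest CV
errors" is defensible); the final model is refit on all training pixels
at the chosen penalty. Fold fits run at relaxed tolerance (1e-5
objective, 1e-4 KKT) — penalty selection compares integer error counts
and is insensitive to the last digits of fold solutions — while the
final refit uses the tight defaults. The CV grid default is 30 lambdas
down to `lambda_max * 1e-3`, coarser than the full path: the CV error
curve is flat near its minimum and a finer grid only re-finds the same
plateau.

### Customized training for mixed samples

Mixed-histology samples (tumor infiltrating glands or stroma) sit off
the pure-class training manifold, and batch effects push them further.
`customized_fit_predict()` implements the customized-training variant:
training and test pixels are clustered jointly (k-means on the
standardized union; k-means++ seeding, 10 restarts, best within-cluster
sum of squares, fixed seed), and each cluster holding test pixels gets
its own lasso — its own CV over the training patients present in the
cluster, hence its own feature list — fitted on that cluster's training
pixels only. Defaults: `G = 3` clusters (one per tissue class), and a
cluster must hold at least 30 training pixels of every class and two
patients to get a local model, else it falls back to the global model;
the floor exists because a near-single-class customized training set
would fit a degenerate local classifier. With `G = 1` the procedure
reduces exactly to the global model. Clustering is per test sample, not
over all test samples jointly — the procedure is defined sample-wise,
and pooling test samples would let one sample's batch structure distort
another's clusters.

### Evaluation

`confusion_matrix()` + `agreement_report()` score predictions against
pathology: per-class agreement $100\,d_k/n_k$ with binomial standard
error $100\sqrt{p(1-p)/n_k}$, overall agreement over all pixels. This SE
convention reproduces, cell for cell, the published agreement tables
packaged with this module (`load_reference_confusion()`), which is how
it was validated. Full precision is kept internally; the display
convention rounds agreement to 0.1 and SE to 0.01. `merge_classes()`
folds glands + stroma into one normal class for the two-class reading.
Sample-level calls: `majority_rule_verdict()` (cancer iff strictly more
than 50% of pixels are predicted cancerous), `composition_agreement()`
(per-region predicted percent cancer versus the pathologist's visual
percent composition, pass within 10 points by default), and
`margin_report()`, which flags a margin positive above a threshold
percentage of cancer pixels — default 1%, deliberately below the ~2%
pixel-level error floor seen on large normal margins, so that
single-digit-percent cancer calls are surfaced for review rather than
absorbed. The qualitative "spatial distribution" criterion used for
mixed samples is implemented as percent-composition agreement;
`render_prediction_map()` supports the visual comparison, and a
region-overlap score would be an extension, not a reimplementation.

## The synthetic cohort generator

No public DESI-MSI dataset accompanies the three-class pancreatic
problem, so `generate_cohort()` builds cohorts with the statistical
structure the analysis assumes, making every downstream stage testable:

* **Templates.** Each class is a sum of Gaussian peaks (default width
  0.15 m/z ≈ two channels, placing each lipid inside a predictable
  half-unit bin) at the marker m/z values listed above, scaled by a
  total abundance of 100 (glands), 80 (cancer) and 25 (stroma) counts —
  the stroma scale deliberately lowest, reproducing its weak total ion
  signal and making it the hardest class, as in real tissue.
* **Mixing.** A tissue layout partitions the grid into rectangular
  regions with composition vectors. Pixel truth labels are sampled from
  the region composition (cell-level mixing at 200 µm), and each
  pixel's expected spectrum blends its label's template with the
  region-mixture template at weight β = 0.3, emulating partial-volume
  signal bleed; with noise off, mixtures are exact convex combinations
  of templates, which the tests exploit.
* **Noise.** Per-pixel log-normal factor with CV 0.8 (mean 1), additive
  baseline of 3 counts, Poisson shot noise on the resulting counts, and
  a per-patient, per-peak log-normal multiplier with SD 0.25 — the
  patient effect is the only thing distinguishing patients when all
  else is fixed, which is exactly what patient-grouped CV needs to be
  tested against. The defaults were calibrated so that held-out
  synthetic accuracy lands near the levels reported for real tissue
  (overall high-90s, stroma near 80%) and then frozen: with gentler
  noise the three classes separate perfectly, which would make the
  evaluation machinery untestable against a realistic error structure.
* **Default cohort.** 25 patients, one 45×45 sample each (~2,000
  pixels), three-region training geometry of roughly 62% glands / 26%
  cancer / 12% stroma — echoing the strong glands ≫ cancer ≫ stroma
  imbalance of real cohorts while keeping enough stroma pixels to
  train on. Regions are clear-diagnosis rather than chemically pure
  (dominant class ≥ 90%, and the stroma strip carries 25% interleaved
  glands cells): combined with partial-volume blending this is what
  makes stroma genuinely hard, mirroring why it is the hardest class on
  real tissue. Documented seed 20130227.

What the generator does **not** emulate: chemical noise and background
ions from the glass slide, isotope envelopes and adducts, spatial
correlation of noise beyond region structure, instrument drift within a
scan, and histology classes outside the three (its `excluded` label
exists only in masks). Passing synthetic tests therefore demonstrates
the pipeline's statistical machinery — not instrument-level robustness
on real tissue.

## Problem sizes used by the test suite

The acceptance-style experiments run at the default study conditions:
25 training patients plus 3 held-out patients at 45×45 (≈ 42,000
training pixels × 2,220 features) for the held-out agreement check,
with the CV grid at 10 lambdas over roughly two decades (the CV error curve is
flat across that plateau, so a finer or deeper grid only re-finds the
same choice at several times the cost). The customized-training
comparison uses 8 training patients (20×20) and 20 mixed test samples
(16×16, 20% tumor in stroma, amplified per-sample batch effects) on the
short 121-channel test axis — the method comparison needs the batch
structure, not the full axis. The solver-correctness check runs 21
random problems of at most 6 features and 60 points against an L-BFGS-B
oracle on the split-variable reformulation of the L1 objective. These
sizes are the package's chosen trade-off between statistical resolution
and a test suite that runs in minutes.

## Known limitations

* The text dialect and CSV masks are the only interchange formats;
  vendor raw files and imzML are out of scope (conversion happens
  upstream).
* The solver targets dense feature matrices of this problem's scale
  (thousands of features); it is not tuned for millions of features or
  sparse inputs.
* Customized training assumes the global model is a sensible fallback;
  when batch shift is so large that clustering itself fails, both
  approaches degrade together.
* Margin flagging is a fixed-threshold rule on pixel fractions; it does
  not model spatial contiguity of cancer calls, which a pathologist
  would weigh.
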