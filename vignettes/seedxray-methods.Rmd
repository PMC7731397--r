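---
title: "Classifying seed viability from X-ray radiographs: models and design choices"
author: "seedxray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying seed viability from X-ray radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A filled, viable seed shows a regular, uniformly bright endosperm in a 2D
X-ray projection image; a deteriorated seed shows internal air spaces (dark
cavities) or an irregular, partially filled endosperm. `seedxray` implements
a complete machine-vision pipeline for turning single-seed radiographs plus
germination-test labels into a binary classifier (*viable* vs.
*nonviable/abnormal*): image enhancement, six handcrafted texture-feature
families, Fisher-score guided sequential forward selection (SFS),
discriminant and nearest-neighbour classification under stratified 10-fold
cross-validation, six-way geometric augmentation with leakage-safe splits,
and a small from-scratch convolutional network baseline.

Because real seed radiograph collections are typically private, the package
ships a **synthetic radiograph generator** as a first-class, tested module.
It defines the study conditions under which every downstream stage is
validated.

## The synthetic generator

`generate_seed()` renders one 224 x 224 image (other square sizes are
accepted for reduced-scale work):

* **Geometry.** An ellipse with uniformly random orientation whose semi-axes
  span 30--60 % of the frame, mimicking magnified single-seed crops. A coat
  rim (outer 18 % of the radius) is brighter than the endosperm plateau.
* **Polarity.** The seed is bright on a dark background: higher X-ray
  attenuation is rendered bright. This is a fixed, documented convention;
  masking is polarity-aware, so datasets digitised the other way around
  still segment correctly.
* **Pathology.** `air_space_fraction` (alpha) places elliptical dark blobs
  inside the endosperm; blob radii are bisected so the merged blob area hits
  alpha of the endosperm area to within 0.5 %. `irregularity` perturbs the
  boundary with low-order random harmonics. With `alpha = 0` and
  `irregularity = 0` the generative law is *identical* to the viable class
  -- the null regime used for calibration checks.
* **Degradation.** Gaussian point-spread blur (`blur_sigma`, default 1 px)
  followed by additive Gaussian noise (`noise_sd`, default 0.02), clipped to
  [0, 1]. This is the simplest radiograph-like degradation; no physical
  X-ray transport is simulated.
* **Reproducibility.** All randomness flows from one integer seed through a
  splittable per-image counter, so a manifest regenerates bit-identically.

Default intensities (coat 0.85, endosperm 0.62, air-space contrast 0.35)
were chosen once as plausible for soft X-ray projections of oilseed-sized
samples: the endosperm clearly above background (0.08), the coat the
brightest structure, and air spaces well below the endosperm minus three
noise standard deviations so they are unambiguous at the default noise
level. Published sources give no quantitative air-space description, so
these are calibration choices of this package, not literature facts.

What the generator does *not* emulate: embryo substructure, cultivar-specific
shape families, scanner artefacts (scatter, heel effect, detector
non-uniformity), or the label noise of germination tests on morphologically
normal but chemically deteriorated seeds. Passing tests therefore show the
pipeline's statistical machinery works end to end; they do not certify
real-data accuracy.

## Preprocessing

`crop_seeds()` cuts supplied rectangles out of multi-seed scans and
resamples each to 224 x 224 with bilinear interpolation. `compute_mask()`
thresholds by Otsu's between-class-variance criterion on a 256-bin
histogram, fills holes and keeps the largest connected component, leaving
exactly one foreground region. Polarity is decided by border majority (the
seed never touches the frame edge); a tie falls back to the side containing
the central pixel. We deliberately do not use the central pixel as the
primary rule: a dark air-space blob at the image centre would invert it.

`enhance_sets()` builds the three derived images used everywhere downstream:

* `set_A = image / max(image)` (max normalization),
* `set_B = clip((set_A - mean) / sd * s + 0.5, 0, 1)` with contrast gain
  `s = 0.15` (about +/-3.3 sd of usable span; configurable) -- the mapping
  into display range is a package choice, centred at mid-gray,
* `set_C` = 3 x 3 median filter of `set_B` with replicate padding (an exact
  comparison-network median, preserving the image size contract).

The mask is computed once per seed, on `set_A`, and reused for all three
sets; whether per-set masks were ever intended is ambiguous in the source
material, and a single mask guarantees that per-set features describe the
same pixels.

## The six feature families (348 per image, 1044 per seed)

| family | count | definition |
|---|---|---|
| intensity | 6 | mean, sd, skewness, excess kurtosis, min, max of masked pixels |
| LBP | 234 | 8-neighbour uniform (u2) codes at radii 1--4; 58-bin histogram per radius (232) + pooled energy and entropy |
| Gabor | 67 | 4 frequencies (0.25 to 0.03125 c/px, one-octave ladder) x 8 orientations; masked mean magnitude + energy per filter (64) + total energy J, pooled mean, pooled sd |
| contrast | 5 | Michelson, RMS, Weber vs. background, range, IQR |
| Haralick | 28 | GLCM at distance 1, offsets 0/45/90/135 degrees, 32 grey levels quantized over the masked range; 14 statistics x (mean, range) over offsets |
| local FFT | 8 | 4 radial bands of the masked image's spectrum: energy fraction + magnitude-weighted circular mean phase per band |

The per-family totals are a fixed contract (6/234/67/5/28/8 = 348 per
enhancement set; 1044 per seed) enforced at extraction time, while every
parameter is overridable through `feature_bank()`. The exact internal
parameterization (radii, bin schemes, frequency ladders, band edges) is this
package's documented default: published selection tables pin the totals but
not the allocation, so the defaults reproduce the totals and keep each
family's conventional construction.

Numerical conventions worth knowing:

* LBP bits are set on *strictly greater* neighbours, so a constant region
  maps to the all-zeros uniform code; neighbours are sampled by bilinear
  interpolation on a circle, and non-uniform codes contribute to the
  normalizer (and the pooled statistics) but have no bin of their own.
* Degenerate statistics (correlation at zero variance, ratios with zero
  denominators, phases of empty bands) are defined as 0, keeping vectors
  finite and fixed-length on any input.
* For speed, extraction crops to the mask bounding box plus an 8-pixel
  margin before computing features. All features are masked-region
  statistics, so this only fixes the FFT/Gabor grid size, deterministically.

## Feature selection

`fisher_score()` ranks features by `J = (mu1 - mu2)^2 / (s1^2 + s2^2)` with
population class variances; `J` is affine-invariant and 0 iff the class
means coincide. `sfs()` runs greedy sequential forward selection with a
cross-validated classifier accuracy as the wrapper objective. How the filter
and the wrapper interact is an open design point; this package uses the
Fisher score to **pre-rank and prune** the candidate pool (default 150),
then lets SFS wrap CV accuracy, which matches the "search strategy +
objective function" framing and keeps desk-scale runtime. Ties break toward
the higher Fisher score, then lexicographic name order, making traces
bit-reproducible. The search runs to `max_k` (default 60) and reports the
first accuracy maximum.

`fisher_lda_cv()` is a deliberately leaner reference evaluation used for
calibration properties: the Fisher ranking is recomputed *inside every
training fold* and only the per-fold top-k features feed an LDA fit. Because
no information from held-out folds touches selection, the estimate is
unbiased: under the null regime it concentrates at 50 %.

## Classification and uncertainty

`fit_lda()` / `fit_qda()` are Gaussian discriminants (shared vs. per-class
covariance) with a small ridge `eps = 1e-6 * trace/p` so early
high-dimensional experiments (p near n) stay solvable; posteriors are exact
softmax of the discriminant scores. `fit_knn()` votes over the 5 nearest
Euclidean neighbours with ties resolved by the nearest neighbour's class.
Features are z-scored with training-fold statistics before any classifier.
Priors default to empirical class frequencies (balanced by construction in
synthetic cohorts).

`cross_validate()` builds stratified folds (per-fold class counts within one
sample of proportional) deterministically from a seed. The reported band is
a 95 % normal approximation over the fold accuracies,
`mean +/- 1.96 sd / sqrt(folds)`, clipped to [0, 100]. A binomial interval
on pooled predictions would also be defensible; the fold-based band is the
default because it matches the symmetric confidence bands conventionally
printed next to fold-averaged accuracies, and `cv_report()` exposes the
arithmetic for alternative inputs.

## Augmentation and splitting

`augment_six()` produces exactly six variants per image -- rotation,
horizontal reflection, x/y translation, x/y scaling -- so 1282 source images
yield 7692 augmented images; the original is not among the six. Ranges
(+/-25 degrees, +/-10 px, 0.9--1.1) are mild and label-preserving, and are
package choices since no ranges are published. Translations are rounded to
whole pixels (exact shifts); rotation and scaling use a bilinear affine warp
that reproduces the input bit-for-bit at identity parameters.

`split_dataset()` partitions 70:15:15, stratified by label, with **source
grouping**: all variants of one image land in the same partition. This is
stricter than a plain random split and prevents augmentation leakage --
near-duplicates of a training image can never appear in the test set.
Cumulative rounding across classes keeps each partition's total at the exact
ratio while per-class counts stay within one item of proportional.

## The small ConvNet

`train_convnet()` implements the baseline network in plain R (im2col matrix
multiplication): repeated blocks of 3 x 3 stride-1 same-padded convolution,
ReLU and 2 x 2 max-pooling, then one fully connected layer and a 2-way
softmax, trained with Adam on cross-entropy. Depth and widths (3 blocks of
16/32/64 channels, lr 1e-3, 20 epochs) are package defaults chosen for
minutes-scale CPU training; all are configurable, and
`convnet_map_sizes()` exposes the spatial bookkeeping (224 halves to 112,
56, 28). Analytic gradients are verified against finite differences in the
test suite. Grayscale input is the native path; `pseudo_color()` replicates
channels for RGB-only architectures but is unused by the small net.
Transfer learning of large pretrained networks is out of scope: it would
require externally trained weights.

## Problem sizes used by the test suite

Simulation-based properties run at reduced, fixed scales chosen once:

* end-to-end effect-size monotonicity and null calibration: 100 seeds per
  class at 112 px, alpha in {0, 0.05, 0.15, 0.3}, 3 repeats, evaluated with
  fold-honest Fisher(top-12)+LDA 10-fold CV;
* the label-permutation control reuses the strongest-effect cohort;
* augmentation arithmetic runs the full 1282 -> 7692 count on 32 px frames;
* the pipeline smoke tests use 10--12 seeds per class at 96 px.

The acceptance script (`scripts/acceptance.R`) regenerates its cohorts from
a command-line seed and recomputes every reported number at run time.

## Known limitations

* Synthetic morphology is a two-class caricature; cultivar differences are a
  single intensity shift, and "abnormal but filled" phenotypes are only
  approximated by boundary irregularity.
* Feature allocation inside the LBP/Gabor/FFT families matches published
  totals, not necessarily any original internal layout; selected-feature
  *names* are therefore comparable only through their family/set tags.
* The CI band treats fold accuracies as independent; they are not, so the
  band is approximate.
* The ConvNet is a correctness-first reference implementation; it is not
  optimized for large images or datasets.
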