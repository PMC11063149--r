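---
title: "How pixelfold works: folding tables into pseudo-images, training, and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How pixelfold works}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-dimensional tabular data — bulk or single-cell expression matrices with
tens of thousands of genes, or any observations-by-features table — are
usually analysed after aggressive filtering and dimension reduction. Small
but systematic perturbations carried by a handful of features are exactly
what such preprocessing removes. `pixelfold` takes the opposite route: it
keeps every feature, maps each one to exactly one pixel of a square
"pseudo-image", trains a 2D convolutional network to classify the images,
and then asks the trained network *which pixels mattered* via gradient-based
attribution. Because the feature-to-pixel map is a bijection, per-pixel
attribution scores translate back to named features with single-feature
resolution.

## Folding

For `F` features the fold uses the smallest square that can hold them:
`side = ceiling(sqrt(F))`, filling row-major and zero-padding the last
`side^2 - F` pixels. A 19,319-feature table therefore becomes a 139 x 139
image with 2 padding pixels, and 18,225 features fold exactly into 135 x 135.
Padding at the tail (rather than interleaved) keeps the pixel-to-feature
back-map trivial, and padding pixels are excluded from every ranking. An
optional index file (`feature_name, rank`) reorders the fold; by default the
column order of the input file is used. The fold spec records the
permutation, so folding with any order remains exactly invertible.

Before folding, each feature is normalised independently: shifted to be
non-negative if it has negative values, transformed by `log1p`, then min-max
scaled to `[0, 1]`. `log1p` is the natural choice for expression-like data
(zeros stay zero, heavy right tails are compressed) and both maps are
monotone, so within-feature ranks are untouched; constant features map to
zero. Normalisation statistics are computed on the full table before any
train/test split. That is a deliberate, documented trade-off: the per-column
min/max leak no label information, and computing them once keeps every
iteration's images identical so attribution maps can be accumulated across
iterations.

## The synthetic benchmark

The built-in needle-in-a-haystack (NIHS) generator emulates the benchmark
the pipeline is designed for: by default 10,000 observations of 18,225
variables, all `Uniform[0, 1)`, except two planted variables whose values
fall in class-conditional sub-ranges — variable 20 (0-based; column 21) in
`[0.00, 0.20)` for class 0 versus `[0.20, 0.40)` for class 1, and variable
17,998 (column 17,999) in `[0.10, 0.20)` versus `[0.25, 0.35)`. Ranges are
half-open, which keeps the class supports disjoint at the shared endpoint
0.20; a single threshold on the first planted variable is a perfect
classifier, which the tests use as an independent oracle for what a
successful recovery must find. Classes are balanced by default (the split is
configurable); labels are assigned by largest-remainder counts and shuffled.
When `n_features` is not the canonical 18,225 and no informative spec is
given, the same two range pairs are planted at column 21 and at the same
offset from the end (`F - 226`), falling back to `F/3` and `2F/3` for very
small tables — chosen once so that small configurations remain valid without
silently changing the benchmark's character.

What the generator does *not* emulate: correlated features, batch effects,
heavy-tailed count noise, class imbalance beyond the configured proportions.
A pipeline that passes the NIHS recovery test has demonstrated sensitivity
to isolated low-amplitude signals in independent noise — not robustness to
the dependence structure of real expression data.

Two further generators exist purely to exercise the trainer quickly:
`generate_toy_patterns()` (class-specific rectangle templates plus Gaussian
noise, clipped to `[0, 1]`) and `shuffle_pixels()`, which applies one seeded
pixel permutation identically to every image. The shuffle experiment probes
a property the whole approach relies on: a CNN's ability to classify
*dispersed* patterns, since a folded table has no meaningful local geometry
to begin with.

## The network

No deep-learning framework is assumed: the package carries a compact
reverse-mode convolutional engine on dense base-R arrays (channel-first
tensors; stride-1 convolutions evaluated as shift-and-multiply BLAS
contractions; batch normalisation; separable adaptive average pooling; Adam).
Its correctness is pinned by finite-difference gradient checks in the test
suite, for both parameter and input gradients — the latter is what
attribution consumes.

Three architectures share one code path and all accept any input side via
adaptive pooling ahead of the linear head:

* `resnet_small` (the desk-scale default): 3x3 stem and two residual blocks,
  8 channels, *stride 1 throughout*, the raw input concatenated as an extra
  channel, adaptive pooling to a 32 x 32 grid. The design follows from the
  one-feature-per-pixel contract: the class signal lives at specific pixels,
  so a compact network must not destroy positional resolution. Deep
  downsampling networks recover absolute position through depth and padding
  effects; a two-block network cannot, so it keeps resolution instead. The
  input-skip channel gives the head direct access to raw pixel intensities
  (a built-in logistic-regression-on-pixels path) while the convolutional
  channels supply local context; gradients — and hence attributions — flow
  through both.
* `resnet18`: the conventional 18-weight-layer residual stack
  (64/128/256/512, two blocks per stage) with average-pool downsampling and
  a global 1 x 1 pool. It is the configuration default, appropriate when
  images are large; training it in this R engine is slow and the desk-scale
  experiments use `resnet_small`.
* `linear`: adaptive pooling straight into the head — a multinomial logistic
  baseline, also used by the attribution unit tests because its gradients
  are known in closed form.

Training uses softmax cross-entropy and Adam with decoupled weight decay on
weight matrices (defaults: learning rate `0.01`, batch 16, decay `0.03`).
These defaults are deliberately aggressive: the regime this pipeline targets
is few epochs over data whose informative signal sits in a handful of
pixels among thousands of noise pixels. Small batches buy more optimiser
steps per epoch; the informative weights, which receive a *consistent*
gradient, then outgrow the noise weights, whose random-walk accumulation is
further suppressed by the decay. The pooled head features pass through a
batch-normalisation before the linear classifier — per-feature
standardisation, without which the logistic head converges too slowly to
respect tight epoch budgets. An iteration stops early once held-out accuracy
reaches `accuracy_target` (default 0.95) — continued training past that
point mainly risks overfitting.

## Iterations, convergence, attribution

Each pipeline iteration draws a fresh stratified split (held-out fraction
0.375 by default, i.e. 3,750 of 10,000), trains a freshly initialised
network, and computes attributions only for *correctly classified held-out
samples*, toward their true class. Restricting to correct held-out samples
keeps the maps grounded in generalising behaviour rather than memorisation.
Every random stage draws its seed deterministically from
`(seed, iteration, stage)`, so whole runs are bit-reproducible.

Across iterations the per-sample attribution maps accumulate with equal
weight (an iteration that classified more samples correctly contributes
proportionally more samples, not more weight per sample). The pipeline stops
early when the best held-out accuracy changes by less than
`convergence_tol` (default 0.005) between successive iterations *and* the
accuracy target has been met; otherwise it runs `max_iterations`. Requiring
the target prevents a chance-level model from "converging" merely by being
stably bad; setting `accuracy_target = 0` recovers a purely
tolerance-driven stop.

Attribution methods: integrated gradients (default; all-zero baseline,
midpoint rule with 8 path steps — ample for these nearly-piecewise-linear
small networks) and plain saliency as the fast alternative. Per class, the
element-wise mean of *absolute* attribution is taken — signed means can
cancel across samples even when a pixel is consistently influential.
Classes with no correct samples yield an all-zero matrix and are flagged.
Ranking maps every non-padding pixel back to its feature, sorts by mean
score descending, and breaks ties by ascending feature index (deterministic
output for degenerate maps). Besides the per-class rankings an `"overall"`
ranking averages the class means weighted by contributing sample counts.

## Numerical and degenerate-input choices

* Empty cells in input files are read as 0 (and counted); the only filtering
  performed removes rows and columns that are entirely zero — evaluated
  simultaneously, which makes the filter idempotent. Filtering everything is
  an error, as is a non-numeric feature cell (categorical features must be
  encoded upstream).
* Label codes are assigned by lexicographic order of the distinct label
  strings, so runs do not depend on file row order.
* Constant columns normalise to zero rather than NaN.
* `ceiling(sqrt(F))` is computed with an integer correction loop so perfect
  squares never suffer floating-point off-by-one.
* Class-stratified splits use largest-remainder rounding so the held-out set
  size is exact and per-class proportions are within one observation.
* A non-finite training loss aborts with the epoch and learning rate in the
  message rather than silently diverging.

## Scale of the shipped experiments

The test suite and the worked examples run at desk scale, chosen as the
smallest sizes at which every claim is still meaningfully exercised: needle
recovery on 2,000 x 1,024 (32 x 32 images, 2 iterations), shuffle invariance
on 1,000 28 x 28 toy images, property checks at a few hundred observations.
The full 10,000 x 18,225 generator run is exercised for range fidelity; a
full-size training run works the same way but takes correspondingly longer
in a pure-R engine.

## Known limitations

* The engine is CPU-only, double-precision, and single-image-format
  (square, one channel); it is a faithful but deliberately small
  implementation, not a general framework.
* The adjacency structure a 2D convolution exploits is an artefact of the
  fold; neighbouring pixels are arbitrary feature pairs. That is exactly why
  attribution, not convolutional locality, carries the interpretive weight.
* Attribution scores are relative; they rank features but are not effect
  sizes.
* The self-supervised/bottleneck clustering mode of the broader approach is
  out of scope here; the pipeline is supervised only.
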