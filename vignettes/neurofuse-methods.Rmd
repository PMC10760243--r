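---
title: "Voxel-wise intensity projections and multimodal 3D CNN classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise intensity projections and multimodal 3D CNN classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurofuse)
```

## The problem

Resting-state fMRI decomposed by spatially constrained ICA yields, for each
subject, a stack of K intrinsic connectivity network (ICN) spatial maps — in
full-size pipelines K = 53 maps on a 53 × 63 × 52 grid at 3 mm isotropic.
Classifiers over neuroimaging volumes, however, expect a small number of
3D channels.  `neurofuse` implements a voxel-wise intensity projection that
collapses the K maps into single volumes, fuses them with gray-matter
density from structural MRI, and classifies subjects (Alzheimer's disease,
mild cognitive impairment, cognitively normal) with a multi-channel 3D
convolutional network, attributing decisions back to voxels with guided
backpropagation.

## Voxel-wise intensity projections

For component values $x_1, \dots, x_K$ at a voxel, the three projections
are

- $\max_k x_k$ — the most activating network (`max_icn`),
- $\lvert \min_k x_k \rvert$ — the most "absent" network (`abs_min_icn`),
- $\max_k \lvert x_k \rvert$ — the most extreme network regardless of sign
  (`max_abs_icn`).

They satisfy, voxel-wise and exactly,
$\max_k |x_k| = \max(\max_k x_k,\, |\min_k x_k|)$, are invariant to
permutations of the components and equivariant to positive rescaling; the
test suite asserts all three properties on random stacks.  Projections are
computed on raw component values; masking and normalization come
afterwards, so any standardization of the component maps is the caller's
responsibility.

## Masking, normalization, channel construction

One binary mask per subject is computed from that subject's own gray-matter
volume: a voxel is kept iff its density is strictly greater than 0.03.  The
same mask is applied to all of the subject's channels.  Min-max
normalization then maps the in-mask range onto $[0, 1]$ (out-of-mask voxels
are exactly 0).  Min/max are taken within the mask, not over the whole
array — outside voxels are background and would otherwise pin the minimum
at 0 regardless of tissue values.  A constant in-mask volume has no range;
it normalizes to all zeros with a warning rather than an error, so batch
pipelines survive pathological inputs.

Three constructions feed the classifier:

1. **unimodal** — one masked, normalized modality (gray matter, a
   projection, ALFF or fALFF);
2. **two-channel** — masked, normalized gray matter first, projection
   second (order is semantic, not sorted);
3. **fused** — with $s$ and $v$ the normalized gray matter and projection,
   the channels are $[s \cdot s,\; s \cdot v,\; v \cdot v]$, each product
   re-normalized by min-max *after* the multiplication.  Normalizing after
   each modality and again after each product keeps the two modalities on
   an equal footing in the fused channels.

## The classifier

`cnn_config()` describes an AlexNet-lineage 3D network: repeated
[3D convolution → batch normalization → ReLU → (max pooling)] blocks,
global adaptive average pooling, two fully connected layers with ReLU and
dropout, and a linear layer emitting one logit per class.  Defaults: filter
counts 64-128-192-192-128, max pooling after blocks 1, 2 and 5, dropout
0.5, fully connected widths 128/64.  The searched convolution settings are
kernel-stride-padding 5-2-0 and 3-2-1.  The default max pool is kernel 3 /
stride 2 / padding 1 — the overlapping AlexNet pool plus one voxel of
padding, which keeps the five-block stack feasible on both the 53 × 63 × 52
grid and small synthetic grids; geometry is validated at the first forward
pass and an input too small for the stack fails with the offending stage.
Adaptive average pooling (to 1×1×1 per feature map) makes the fully
connected head independent of grid size, so one configuration serves any
sufficiently large grid.

The engine is implemented in the package itself: convolutions are evaluated
as im2col matrix products with memoized index geometry, and the backward
pass is the exact adjoint (checked against central differences to ~1e-11 in
the test suite).  Weights use Kaiming-style He-normal initialization with a
recorded seed; biases start at zero.  In eval mode dropout is disabled and
batch normalization uses running statistics (momentum 0.1), making forward
passes bit-reproducible.

## Training protocol

Cross-entropy is minimized with Adam.  Validation accuracy is monitored
each epoch: no improvement greater than `min_delta` (1e-4) for
`plateau_patience` (5) consecutive epochs halves the learning rate
(factor 0.5); no improvement for `early_stop_patience` (20) epochs stops
training, and the parameters of the best validation epoch are returned.
The searched grid is five learning rates (0.1 … 1e-5), five batch sizes
(4 … 64) and the two kernel combinations — 50 configurations, enumerated by
`default_hyper_grid()`; `grid_search()` selects on mean validation accuracy
only, leaving the held-out test sets untouched.

Splits come from stratified repeated subsampling (`make_split_plan()`):
each fold is an independent random draw, not a partition.  With the floor
rule, validation and test cohorts each receive $\lfloor n/\text{folds}
\rfloor$ subjects (58 from n = 466 at 8 folds, leaving 350 for training);
explicit sizes are also accepted (95/95 from n = 730, leaving 540), since
printed study splits do not always follow a single formula.  Within every
cohort, per-class proportions match the full cohort to within one subject
via largest-remainder allocation.

Metrics are reported on a 0–100 scale: accuracy, balanced accuracy (mean of
per-class recalls), macro-averaged F1/precision/recall (macro, not
weighted — this choice changes the numbers and is stated prominently), and
AUC (binary: ROC area of the AD class, computed by the rank/Mann-Whitney
formula; three-class: macro one-vs-rest).  `aggregate_folds()` reports
mean ± sample standard deviation across folds.  `chi_squared_compare()`
pools correct/incorrect counts into a 2 × 2 table and applies Pearson's
test with no continuity correction.

## Saliency

`guided_backprop()` differentiates the target-class logit with respect to
each input channel; at every ReLU the backward signal is zeroed where the
forward activation was non-positive or the incoming gradient negative.  In
a ReLU-free network this reduces to the plain gradient (asserted against
the analytic weight map of a linear model).  Maps are stored signed; for
cohort summaries the default takes magnitudes before smoothing so positive
and negative attributions do not cancel (`signed = TRUE` averages raw
maps — both modes are tested).  `aggregate_saliency()` masks, smooths at
FWHM 10 (interpreted in mm: σ ≈ 1.416 voxels at 3 mm; a voxel-unit flag
exists) and averages across subjects; smoothing and averaging commute, and
the test suite asserts it.  The target class defaults to the subject's true
label (a flag allows the predicted one).  Visualization thresholds at an
in-mask quantile, default 0.9, applied only at rendering time.

## ALFF / fALFF baselines

Per voxel the series is linearly detrended (mean and trend removed), Fourier
transformed, and summarized over DFT bins whose centre frequency lies in
the closed band 0.01–0.08 Hz (the standard low-frequency band; configurable):
ALFF is the mean amplitude over in-band bins, fALFF the in-band amplitude
sum divided by the sum over all positive-frequency bins (DC excluded), with
0/0 defined as 0.  ALFF is homogeneous of degree 1, fALFF scale-invariant
and monotone in band inclusion.  One numerical subtlety: an on-bin sinusoid
is generally *not* orthogonal to a linear trend, so detrending a generic
sine leaks power across bins; the exact fALFF = 1 check uses the
trend-orthogonal phase of the on-bin sinusoid.  No global-mean scaling is
applied to ALFF maps — the downstream min-max normalization supersedes it.

## The synthetic cohort generator

Real data for this problem is access-restricted, so `generate_cohort()`
draws aligned cohorts with known ground truth.  Gray matter is a fixed
template — a smooth brain envelope plus Gaussian blobs at fixed fractional
coordinates, so any grid of at least 8 voxels per axis works.  Two
designated "atrophy" blobs play the role of hippocampus/amygdala (no
anatomical claim): their amplitude is scaled by $1 - \text{gm\_effect}$ for
AD and $1 - \text{gm\_effect}/2$ for MCI.  Each of the K component maps has
one positive and one negative Gaussian lobe, so the max- and
|min|-projections carry distinct information; the two designated components
place their signal lobes on the atrophy blobs.

The class effect on the components is a *reduction* of the designated lobe
amplitude (by icn\_effect/2 for AD, half that for MCI).  The direction
matters: because each channel is min-max normalized within the mask, an
amplitude increase at the designated lobe simply becomes the global
maximum and is normalized to 1 for every class — no between-class signal
survives.  A reduction (hypoactivation) is preserved by normalization,
since the global maximum is set by the unshifted components elsewhere.

Noise is voxel-independent Gaussian (default sd 0.05 against lobe
amplitudes of ~0.7–0.8), applied inside the brain envelope so the
background stays zero and the 0.03 gray-matter mask stays clean.  One
cohort seed fans out to per-subject sub-seeds drawn once from the cohort
stream, so cohorts are bit-reproducible.  Synthetic time series place an
in-band sinusoid (the bin nearest 0.05 Hz) at every voxel with amplitude
proportional to the subject's max-abs projection, plus white noise.

What the generator does *not* emulate: spatial noise correlation, scanner
artifacts, head motion, hemodynamics, registration error, or realistic
anatomy.  Passing tests therefore demonstrate the pipeline's correctness
and its ability to recover known, well-separated effects — not expected
performance on clinical data.

## Problem sizes used in the shipped checks

The package's end-to-end check trains on a cohort of 120 subjects (60 AD /
60 CN) on a 24³ grid with K = 8 and strong effects (gm\_effect 0.4,
icn\_effect 1.0), using a compact 8-16-32 filter configuration and three
repeated stratified folds with explicit 80/20/20 cohorts — at three folds
the floor rule would allocate as many subjects to validation and test as to
training, so explicit sizing is the sensible choice.  Under these
conditions the fused three-channel model reaches ~100% held-out accuracy
and never falls below the unimodal gray-matter model, and the unimodal
projection model clears 70% by a wide margin.  These are generator
conditions chosen once, not tuned quantities.

## Known limitations

- The engine is plain R: fine for desk-scale grids (24³–53 × 63 × 52,
  dozens to hundreds of subjects), not for large-scale GPU training.
- Inputs must be pre-aligned on one grid; no registration or resampling.
- Batch normalization details (momentum, plateau window, filter counts,
  dropout rate) are package defaults where the underlying description is
  silent; all are exposed in `cnn_config()` / `train_config()`.
- The chi-squared comparison applies to pooled accuracy counts; a
  chi-squared on AUC values is not a standard construction and is not
  provided.
- A regression head is intentionally out of scope.
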