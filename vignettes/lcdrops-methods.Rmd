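---
title: "Detecting trace amphiphiles in liquid-crystal droplet micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trace amphiphiles in liquid-crystal droplet micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The sensing problem

Micrometer-scale droplets of a nematic liquid crystal (5CB) adopt a
*bipolar* internal configuration in water: the molecular director field has
two surface point defects ("boojums") at opposite poles. Between crossed
polarizers such a droplet shows a characteristic texture — a four-fold
extinction cross, colored concentric interference rings, and two dark
points where the bipolar axis meets the rim. Amphiphilic contaminants such
as PFOA and PFOS adsorb at the droplet interface at concentrations far
below anything a human can see in the image, subtly perturbing the texture.
The analysis task is therefore: given cross-polarized micrographs of
droplet arrays exposed to different water samples, decide which condition
(water matrix, analyte, concentration class) each droplet came from.

`lcdrops` implements the full pipeline: a synthetic micrograph generator
with planted, tunable class effects; droplet detection and cropping;
20-fold affine augmentation; a jointly trained convolutional autoencoder
and classifier with an EMA-normalized combined loss; stratified 5-fold
cross-validated evaluation; transfer learning from a frozen encoder; and
PCA diagnostics of the latent space.

## The synthetic generator

No elastic-continuum simulation is attempted. The renderer uses the
simplest crossed-polarizer transmission model that reproduces the described
phenomenology: pixel intensity inside the droplet footprint is

$$I_c(r, \varphi) \propto \sin^2(2\varphi)\,\sin^2\!\big(s_c\,t(r) + \phi\big),
\qquad t(r) = \sqrt{1 - (r/R)^2},$$

where $\varphi$ is the azimuth relative to the bipolar axis (the
$\sin^2 2\varphi$ factor is the extinction cross), $t(r)$ is the normalized
optical path through a sphere, $s_c$ is a per-channel retardance scale
(scaled by $0.90/1.04/1.17$ for R/G/B, the $1/\lambda$ wavelength
dependence of retardation in waves), and $\phi$ is a ring-phase offset. Two
Gaussian dark spots of adjustable contrast at the rim poles model the
boojums; Gaussian blur models defocus. Fields place 24–30 droplets on a
jittered square grid whose pitch mirrors the stamped-array geometry, which
guarantees non-overlap by construction; a configurable fraction of droplets
is rendered faint or strongly defocused, and Gaussian background noise is
added. Default scale: 800×600 px fields with mean droplet radius 25 px
(the pixel scale of the real instrument is not constrained by anything in
the package, so any consistent scale is acceptable).

One deliberate choice deserves emphasis: the base ring phase is drawn from
a *concentrated* distribution, $\phi \sim N(1.5, 0.4)$, not uniformly on
$[0, 2\pi)$. Droplets from one batch share a typical residual phase set by
material and geometry; statistically, a uniform circular phase would make
any additive phase effect unobservable (a uniform distribution is invariant
under shifts), so a concentrated base distribution is what makes planted
phase effects detectable at all.

### Planted class effects

Condition labels act on droplet optics through additive parameter shifts,
all multiplied by one global `effect_size`:

* PFOA concentration shifts the retardance scale (ring count), with
  magnitude increasing in concentration (0.8 / 1.6 / 2.4 for
  1 ppt / 1 ppb / 1 ppm) and a small defect-contrast shift;
* the water matrix shifts ring phase (0 / 0.5 / 1.0 rad for Milli-Q /
  tap / river water), defect contrast and brightness slightly;
* PFOS shifts defect contrast (+0.12), ring phase (−0.6 rad) and
  brightness (+0.05);
* the PFOA + PFOS mixture effect is the *exact superposition* of the
  PFOA (1 ppt) and PFOS deltas. This superposition is what produces the
  PFOS-predicted-as-mixture confusability that the transfer experiments
  check.

At `effect_size = 0` every label generates statistically identical
droplets (exchangeability), verified by Kolmogorov–Smirnov tests in the
test suite. Magnitudes were fixed once from pilot renders so that
`effect_size` ≈ 1 is a subtle perturbation (single-digit percentage
changes against the natural droplet-to-droplet jitter) and `effect_size`
= 3 is a "large" effect that a converged classifier can exploit reliably;
the tests use 0 / 1 / 3 as their null / medium / large settings.

## Droplet extraction

Detection follows Canny edge detection on a Gaussian-smoothed grayscale
field (σ = 2 px), followed by morphological closing of the edge contours,
hole filling, connected-component labeling, and one bounding box per
component with a circularity score $4\pi A / P^2$. Boxes touching the
image border are discarded as partial droplets. Two implementation details
matter:

* Canny itself (Sobel gradients, four-direction non-maximum suppression,
  double-threshold hysteresis) is implemented in the package, since no
  installed R package provides it; morphology, labeling, shape features,
  blurring, resizing and affine warps all come from `EBImage`.
* The closing step uses a generous disc brush (21 px default): the
  extinction cross interrupts a droplet's rim edge at four points, and the
  brush must bridge those gaps while staying below the distance between
  neighbouring droplets.

Size filtering is *distribution-determined*: cutoffs are empirical
quantiles of the detected box-area distribution of the whole batch, not
fixed pixel constants. The default quantiles are 0.01/0.99 with a
circularity floor of 0.4. Tail quantiles necessarily discard that fraction
of a clean batch, so very tight quantiles would conflict with high recall;
the defaults keep batch-level recall ≥ 95% (measured ≈ 97–100% on default
synthetic fields with precision 100%) while still removing the order-of-
magnitude area outliers that merged or spurious detections produce.
Quality rejection replaces the human judgment of "faint or substantially
out of focus" with two algorithmic thresholds measured on the crop
interior: intensity spread (P95 − P5 ≥ 0.2) and variance-of-Laplacian
sharpness (≥ 1e-4). Thresholds were calibrated on renders of the
generator's default faint (brightness 0.08–0.2) and defocused
(σ = 5–8 px) populations, which they separate cleanly from the nominal
population.

## Augmentation

Each retained crop is expanded into exactly 20 variants by independently
sampled composite affine transforms: rotation uniform in ±180°, shear
uniform in ±10°, and horizontal/vertical flips with probability 0.5, with
out-of-frame pixels filled at the dark-field background level. Rotations
that are exact multiples of 90° with no shear are performed losslessly on
the pixel lattice. Augmentation happens *after* fold assignment so that
variants of one droplet never straddle a train/validation boundary; the
alternative order would leak nearly identical images across the split and
inflate validation accuracy.

## The joint autoencoder–classifier

The encoder has three stages of 3×3 convolution → 2×2 average pooling →
batch normalization → ReLU with channel widths (16, 32, 64), followed by a
linear map to a 128-dimensional latent vector (the documented grid for the
latent width is 32/64/128). The decoder mirrors it; each decoder stage is
nearest-neighbour 2× upsampling followed by a 3×3 convolution — the
resize-convolution form of a stride-2 transposed convolution stage, chosen
because it reuses the verified convolution kernels and avoids checkerboard
artifacts — and the output passes through a sigmoid so reconstructions live
in [0, 1] like the inputs. The classifier head consumes only the latent
vector: two hidden ReLU layers (256, 128) with 20% dropout before the
logits.

Training minimizes the dynamically normalized combined loss

$$L_{\mathrm{total}}(t) = \beta_{\mathrm{recon}}
\frac{L_{\mathrm{recon}}(t)}{\bar L_{\mathrm{recon}}(t)}
+ \beta_{\mathrm{classifier}}
\frac{L_{\mathrm{classifier}}(t)}{\bar L_{\mathrm{classifier}}(t)},$$

with $\beta = 0.5/0.5$, where the running averages follow
$\bar L(t) = \alpha \bar L(t-1) + (1-\alpha) L(t)$ with $\alpha = 0.9$.
Averages update once per epoch from that epoch's mean losses; within an
epoch every minibatch is normalized by the previous epoch's averages, and
the first batch of epoch 1 initializes them. The averages are treated as
constants in the gradient — they are normalizers, not learnable signals —
and are floored at 1e-8 against degenerate near-zero reconstruction
losses. Optimization is Adam at learning rate 0.001; the reference
configuration is 50 epochs with batch size 200, and the classification
loss is weighted inversely to class frequencies (weights normalized to
mean 1; the loss is the plain batch mean of $w_y \cdot \mathrm{nll}_y$).

The whole network is implemented in vectorized base R: convolutions are
single-gather im2col reshapes feeding BLAS matrix products (the input
gradient is the correlation with the 180°-rotated kernel, again as one
gather plus one product), and every backward pass is hand-derived and
pinned by finite-difference gradient tests. One practical consequence of
training at desk scale is that an epoch contains few minibatches, so batch
normalization's running statistics would lag far behind the trained
parameters; after the last epoch the package therefore recalibrates the
running moments with a dedicated pass over the training data before the
model is used in evaluation mode.

## Evaluation

All splitting is at droplet level, stratified by class: per class, droplet
ids are shuffled and dealt round-robin into k = 5 folds, so per-fold class
counts match global proportions within one droplet. Each fold trains a
fresh model (fold-indexed derived seed, identical hyperparameters),
predicts its held-out droplets' raw crops, and contributes to a pooled
confusion matrix (rows = truth). Reported metrics: pooled accuracy
(correct over all validation predictions), per-class accuracy
(row-normalized diagonal), and macro F1 as mean ± SD across folds, with a
class of zero precision + recall contributing F1 = 0. Argmax ties break to
the lowest class index. Chance baselines are 100/k (8.33% for 12 classes,
16.7% for 6, 25% for 4, 50% for 2).

The random-label negative control draws all droplets from one homogeneous
condition, splits them 50/50 into arbitrary "PFAS"/"Control" groups at
droplet level, and runs the identical pipeline; its pooled accuracy should
sit inside the central 99% binomial band around 50%, and anything else
would indicate leakage or bookkeeping errors rather than signal. The blind
test applies a saved model to droplets whose ids are disjoint from
training by construction, and raises an error on any overlap.

## Transfer learning and latent PCA

Transfer freezes a pretrained encoder (the 12-class joint run is the
reference checkpoint), extracts evaluation-mode latent features, and trains
only a fresh classifier head (same architecture, no decoder, no
reconstruction term) with class weighting and the same stratified CV.
Whether the original head's weights could be reused is an open choice;
fresh initialization is the cleaner reading and is what the package does.

`pca_project` runs standard PCA on mean-centered data; explained-variance
ratios divide by the total variance so they are non-increasing and sum to
at most 1, and each component's sign is fixed by making its
largest-magnitude loading positive. Data lying on an exact line yields
ratios (1, 0, 0); the function errors only when the matrix has fewer rows
or columns than requested components, and zero-variance trailing
components simply get ratio 0. A label-permutation test on between-class
centroid distances quantifies the latent-vs-raw separation contrast.

## Problem sizes and what the tests show

The test and acceptance runs use 32 px crops (any multiple of 8 is
supported; 64 px is the package default for full-scale runs), tens of
droplets per class, and single-digit epoch counts — the package's chosen
desk scale. Observed reference points at these scales, all reproduced by
the suite with fixed seeds: binary control-vs-1 ppm at large effect
reaches ≈ 94% pooled accuracy; the 4-class river-water species task
reaches ≈ 69% against 25% chance; the frozen-encoder 6-class transfer
reaches ≈ 56% against 16.7% chance with the PFOS-as-mixture confusion
pattern; zero-effect runs sit at their chance lines; and the random-label
control sits in the 99% binomial band around 50%.

Two test-design notes. The "equal contribution" property of the EMA
normalization is a statement about a stationary loss stream, so the test
realizes the fixed point with noise inputs and arbitrary labels (both
losses plateau) rather than with a separable task whose losses decay
geometrically. The latent-grid property (reconstruction error
non-increasing over 32/64/128) is checked as a trend over three seeded
runs at a scale where the bottleneck binds; at desk scale droplet crops
have low intrinsic dimension, so the differences are modest.

## What the synthetic data does not show

The generator emulates the *statistical structure* of the experiment —
bipolar textures, size dispersion, faint/defocused imaging, background
noise, and class-dependent subtle perturbations with a controllable effect
size — but not the optics of real 5CB droplets: no elastic director-field
physics, no camera calibration, and no attempt to match the color
statistics of the real image corpus. Consequently, passing tests
demonstrate that the pipeline recovers planted effects of a given size
with correct bookkeeping and honest nulls; they do not certify any
particular detection limit on real micrographs, and the real study's
headline accuracies are properties of its experimental image corpus, not
reproduction targets for synthetic data.

## Known limitations

* Pure-R training is CPU-bound; full-scale runs (64 px crops, 50 epochs,
  hundreds of thousands of augmented images) are possible but slow.
* The renderer's extinction cross makes detection masks slightly lobed, so
  the default circularity floor (0.4) is looser than one would use for
  solid discs.
* Weighted cross-entropy uses the plain batch mean of weighted
  per-sample losses; frameworks that divide by the sum of weights differ
  slightly on unbalanced batches.
* `random_binary` labeling lives outside the condition-label type system
  (it is attached by the control itself), and mixture conditions reuse the
  concentration class of their PFOS component.
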