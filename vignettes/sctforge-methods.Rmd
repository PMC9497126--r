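---
title: "Synthetic CT from CBCT: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT from CBCT: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam CT (CBCT) acquired on the treatment machine is the natural image
source for adaptive radiotherapy, but scatter-induced cupping and shading,
haze and noise corrupt its Hounsfield units enough to preclude direct dose
calculation. `sctforge` implements the image-translation approach to this
problem: a fully convolutional DenseNet `G` maps a CBCT axial slice `x` to a
synthetic CT `G(x)` that should match the deformably registered planning CT
(dCT) of the same anatomy, and the interesting scientific question is how
the composition of the training loss affects the fidelity of `G(x)` — in
pixel terms, in image-feature terms, and in recomputed dose.

## Losses

Three loss components operate on intensity-normalized slices (HU clipped to
`[-1000, 2000]` and mapped affinely to `[-1, 1]`, so the dynamic range is
L = 2):

* **L1**: mean absolute pixel difference between `G(x)` and the target.
* **SSIM**: the structural-similarity statistic
  `((2 mu_x mu_G + c1)(2 sigma_xG + c2)) / ((mu_x^2 + mu_G^2 + c1)(sigma_x^2 + sigma_G^2 + c2))`.
  The printed statistic is a similarity to maximise, so the trainable loss
  is `1 - SSIM` — the standard sign convention. The stabilisation constants
  follow the universal convention `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`.
  The formula as written is a global (whole-image-moment) statistic;
  `ssimValue()` offers both that `global` form and the windowed mean-SSIM
  (`gaussian`, window 11, sigma 1.5). During *training* the global form is
  used because its gradient is closed-form; *evaluation* uses the windowed
  form, which is the form practitioners report.
* **Perceptual**: mean squared Euclidean distance between deep feature maps
  of the two images. The extractor is pluggable. The default is a fixed,
  seeded-random four-stage convolutional stack (3x3 convolution, ELU, 2x2
  max-pool per stage): random fixed features preserve the contract of the
  loss — a distance in a nonlinear feature space that penalises structural
  rather than pixel disagreement — without requiring any pretrained weight
  download, and make the loss bit-reproducible. An adapter accepts
  externally supplied stage weights when a pretrained feature bank is
  available. Which stages feed the loss is configurable
  (`perceptualLayers`, default stages 2 and 4); the choice is reported in
  the configuration rather than hard-coded, since no canonical choice
  exists.

The four studied compositions are L1, LP (L1 + perceptual), LS (L1 + SSIM)
and LPS (all three), with unit weights by default: the protocol calls for
balanced weights without giving numbers, and unit weights on
similarly-scaled components are the declared reading.

## Network

`buildNetwork()` constructs the FC-DenseNet: an initial 3x3 convolution;
`nPool` dense-block + transition-down stages; a bottleneck dense block;
`nPool` transition-up + dense-block stages with skip concatenation from the
matching down-path resolution; and a final 1x1 convolution. The transition
down is, in order: batch normalisation, ELU, 1x1 convolution, dropout
(p = 0.2), 2x2 max-pooling. Dense layers are BN -> ELU -> 3x3 convolution
-> dropout, each contributing `growthRate` feature maps; the transition up
is a 2x2 stride-2 transposed convolution applied to the new feature maps of
the preceding block (the classic FC-DenseNet channel economy). The
full-scale default follows the FC-DenseNet56 family (4 layers/block,
growth 12, 5 pooling stages); `tinyNetworkConfig()` (2 pooling stages,
growth 8, 2 layers/block, 16 first-layer channels) is the desk-scale preset
used throughout the tests.

Two implementation choices matter:

* **Padding.** 270 x 270 inputs are not divisible by `2^5`; inputs are
  reflect-padded to the next multiple of `2^nPool` and cropped back after
  the forward pass — the minimal reconciliation of the published input size
  with a pooling architecture.
* **Residual output.** By default the network predicts the *correction*
  added to its input (`G(x) = x + f(x)`), with the final convolution
  initialised to zero so the initial mapping is exactly the identity.
  Artifact reduction is a near-identity problem, and at desk-scale training
  budgets (tens of epochs on tens of slices) a from-scratch
  full-reconstruction network spends its entire budget relearning anatomy.
  The residual form is standard practice in restoration networks and is
  switchable (`residual = FALSE`) for full-scale runs.

The whole engine — convolution, batch normalisation, pooling, transposed
convolution, dense concatenation and their reverse passes — is implemented
in the package (R orchestration over C++ im2col/BLAS kernels). Every
backward path is finite-difference-checked in the test suite.

## Training protocol

`trainNetwork()` follows the reference protocol: Adam (default beta
parameters), initial learning rate 2e-5, 150 epochs, on-the-fly
augmentation, identical hyper-parameters across loss compositions. The
library defaults mirror that full-scale protocol; the desk-scale
experiments in the tests and the acceptance script use 30 epochs at
learning rate 1e-3, batch size 8, which is the standard regime for training
a tiny network from scratch in ~150 optimisation steps.

Augmentation draws, per sample: a horizontal flip (probability 0.5) and a
rotation within +/-10 degrees applied with *identical* parameters to input
and target (pair integrity, asserted in tests; bilinear resampling,
-1000 HU fill), and a gaussian blur applied to the *input only* — blur
models imaging degradation, and blurring the target would silently change
the learning objective. Model selection keeps the checkpoint with the best
validation MAE rather than the last epoch, since a validation split exists
but no selection rule is prescribed.

## The phantom (and what it does not show)

No public dataset accompanies the method, so `phantom_sim` generates the
study conditions: 270 x 270 slices at 1 mm (64 x 64 in the desk-scale
tests), split 50/5/10 into train/validation/test in the proportions of the
full-scale protocol. Anatomy is randomized nested ellipses — air background
(-1000 HU), skull ring (700-1200 HU), brain soft tissue (20-50 HU) with
smooth texture, 2-5 low-contrast lesions (+/-15-30 HU), air cavities. The
CBCT copy is the same anatomy degraded by:

* a multiplicative low-frequency bias field on the attenuation-offset image
  `HU + 1000` — 70% a radial cupping term, 30% seeded smoothed noise with
  correlation length `biasScale`. Applying the field to `HU + 1000` rather
  than raw HU gives cupping of realistic magnitude in soft tissue
  (amplitude parameter = HU error at water);
* additive scatter haze proportional to a wide-kernel blur of the
  attenuation;
* additive Gaussian noise (sigma 10 HU) and a constant 15 HU shift.

Defaults (bias 70 HU, scatter fraction 0.06, noise 10 HU) put the
uncorrected CBCT-vs-dCT MAE at roughly 25 HU — an order of magnitude above
the ~6 HU post-correction residual reported for real data. The mix is
deliberately dominated by *systematic* (removable) error: on a 64 x 64
phantom the skull ring is only 1-2 px of ~2000 HU contrast, so any
blur-style denoising is catastrophic and the iid-noise term is effectively
irreducible at desk scale; calibrating the noise term to ~8 HU of MAE
keeps the headroom in components a correction network can actually
remove. The phantom does *not* emulate detector-specific artifacts,
streaks, truncation, registration error or 3D cone-beam geometry; passing
tests demonstrate the pipeline's correctness and sensitivity, not clinical
performance.

Dose grids are likewise surrogates. `generateDosePair()` builds a reference
field from 2-5 anisotropic Gaussian beam lobes (no narrower than 5 px, so
the grid resolves the beam, with a smooth collimation taper to zero at the
grid edge) and perturbs it controllably — shift, scale, proportional noise
— for validating the gamma machinery. For the ablation harness, where dose
must *respond to HU errors*, `doseFromAnatomy()` applies a deterministic
pseudo-dose operator (seeded lobe fluence times depth attenuation of the
anatomy) identically to dCT and synthetic CT; it mimics the direction of
Monte-Carlo recomputation, not its physics.

## Feature mapping ratio

The feature-level metric runs a keypoint pipeline on both images and
reports matched/detected:

1. **Nonlinear scale space**: Perona-Malik g2 diffusion
   (`c = 1/(1 + |grad|^2/k^2)`), explicit conservative steps (tau <= 0.2,
   Neumann boundaries — the intensity sum is conserved exactly), levels at
   `sigma0 * 2^(i/nSublevels)`. The contrast parameter k is the 70th
   percentile of gradient magnitudes above 1% of the maximum — excluding
   near-zero background gradients, which would otherwise collapse k and
   freeze the evolution.
2. **Detection**: responses are scale-normalized differences of adjacent
   levels (`(L[i+1] - L[i]) * t_mid / dt`, the discrete scale-normalized
   Laplacian). Keypoints are strict 3x3 spatial extrema per response image,
   merged across levels by non-maximum suppression (2 px radius, strongest
   response wins). A strict 3-level scale extremum was evaluated and
   rejected: edge-preserving diffusion makes the scale response of isolated
   structures monotone rather than unimodal, so the cube criterion misses
   true blobs that the per-level criterion finds.
3. **Description**: per keypoint, a scale-proportional patch at the
   keypoint's evolution level is divided into a 4x4 grid; each sub-region
   contributes mean intensity and mean first derivatives. 256 bits are
   pairwise same-channel comparisons under a fixed schedule generated by a
   private linear congruential stream from a packaged constant seed —
   descriptors are therefore machine-stable, invariant to global intensity
   offsets, and complementary under contrast inversion. Images are min-max
   mapped to the 8-bit range before analysis.
4. **Matching**: brute-force normalized Hamming distance with acceptance
   threshold 0.8. A raw distance threshold of 0.8 bits would be degenerate,
   so the threshold is read as a fraction of differing bits; a Lowe-ratio
   mode is also provided. On top of the threshold, a mutual-nearest
   cross-check (ties tolerated, made one-to-one greedily by distance then
   index) guarantees `FMR(x, x) = 1` and `0 <= FMR <= 1`.
5. **Ratio**: matched count divided by the detections in the first
   (synthetic) image by default; `min` and `mean` denominators are exposed
   because the convention is ambiguous.

## Gamma index and dose difference

`gammaMap()` is reference-point-driven with global normalisation: for every
reference point at or above the dose cutoff (default 10% of the reference
maximum), it minimises
`sqrt((Ddiff / (doseDiffPct * maxRef / 100))^2 + (dist / dtaMm)^2)` over
evaluated-dose positions within a search radius of 3x the DTA, bilinearly
interpolated at DTA/10 steps. Offsets are visited sorted by distance so the
search stops once the spatial term alone exceeds the current minimum —
this is an exact, not approximate, shortcut, and the fast path is asserted
equal (1e-6) to an exhaustive brute-force oracle on seeded grids. The mean
absolute dose difference is normalized to the reference maximum over
above-cutoff points, matching the ~0.01 magnitudes conventionally reported;
the normalisation is a configuration switch since the convention is not
universal. Comparisons are 2D per-slice; criteria nest by construction
(pass at 2%/2 mm >= pass at 1%/1 mm).

One analytic subtlety: a uniform 2% dose scaling does *not* fail a 1%/1 mm
criterion everywhere under global normalisation — points below half the
maximum pass on the dose term alone, and gradients let the DTA rescue more.
The tests pin the exact behaviour (total failure on a flat field, partial
failure on lobed fields, always oracle-equal) rather than a folklore
expectation.

## Problem sizes and reproducibility

The desk-scale experiments are sized for a single CPU: 50 phantom cases at
64 x 64 (38/4/8 split), the tiny network preset, 30 epochs for the recovery
experiment and 4 epochs per configuration for the ablation-shape check;
gamma oracle comparisons run on 32 x 32 grids and FMR sweeps on 128 x 128
phantoms. Every stochastic step — phantom generation, weight
initialisation, shuffling, dropout, augmentation — derives from explicit
seeds, and a dataset generated twice from one seed is bit-identical. The
`scripts/acceptance.R` entry point reruns the full pipeline from a single
`--seed` and writes the headline quantities as JSON.

## Known limitations

* The phantom's artifact model is statistical, not physical; absolute
  metric values are not comparable to patient studies.
* Perceptual loss with random features is a valid feature-space distance
  but not a learned-semantics distance; with pretrained weights plugged in,
  numbers will differ.
* The dose surrogate shares no physics with a Monte-Carlo engine beyond
  monotone response to HU error.
* 2D slices only; volumes are treated as slice stacks.
* DICOM input is not supported; NIfTI is the interchange format.
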