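---
title: "Methods: paired longitudinal harmonization of interscanner MRI"
author: "longiharm developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired longitudinal harmonization of interscanner MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Longitudinal brain MRI follow-up often crosses scanners: a patient's
baseline (BL) examination is acquired on one machine and a follow-up (FU)
examination on another. Even with identical nominal sequences, the two
scanners impose different intensity mappings, tissue contrasts, bias fields
and noise levels, and the anatomy that matters — an enhancing lesion, the
grey/white interface — must be compared across that nuisance variation.
`longiharm` implements a paired, cycle-consistent adversarial translation
model that maps FU volumes into the BL scanner's intensity domain (and vice
versa) while preserving anatomy, together with the full surrounding
pipeline: preprocessing, rigid registration, slice-wise inference with
volume re-stacking, a histogram-matching baseline, and a quantitative
evaluation suite.

Because clinical data of this kind are not publicly distributable, the
package ships a synthetic longitudinal phantom generator with complete
ground truth. Everything the pipeline asserts about itself is asserted on
phantoms.

## The model and its objective

Two generators translate between the domains: \(G_A\) maps any input into
the BL domain and \(G_B\) into the FU domain. Two patch-level
discriminators \(D_A, D_B\) score realness in their domain. Both
translation directions are computed in every iteration and the loss terms
averaged across directions. The objective combines three terms:

**Adversarial loss** (log form; raw discriminator scores pass through a
sigmoid, logs are clamped):
\[
L_{adv} = E_x[\log D(x)] + E_x[\log(1 - D(G(x)))]
\]
The discriminator maximizes this printed objective (the implementation
minimizes its negation); the generator minimizes the non-saturating
\(-E[\log D(G(x))]\), which drives \(D(G(x))\) toward the "real" label and
decreases monotonically in it.

**Cycle-consistency loss**: the element-mean L1 distance between an image
and its round trip through both generators,
\(\lVert x - G_B(G_A(x))\rVert_1\), computed for both domains and averaged.

**Original matching loss (OML)**: the four-term L1 penalty that ties every
generator–domain combination of a *registered BL/FU pair* back to the
originals:
\[
L_{oml} = \lVert x_A - G_A(x_B)\rVert_1 + \lVert x_A - G_A(x_A)\rVert_1 +
          \lVert x_B - G_B(x_A)\rVert_1 + \lVert x_B - G_B(x_B)\rVert_1 ,
\]
each term an element mean, summed with equal weight (not averaged over the
four terms). Restricting OML to its two same-domain terms recovers the
classical identity-mapping loss exactly; this subset relation is unit
tested and exposed via the `variant` flag of `loss_weights()` so that the
"with identity loss" and "without identity loss" baselines are the same
code path.

**Final objective**: \(\lambda_{adv} L_{adv} + \lambda_{ccl} L_{ccl} +
\lambda_{oml} L_{oml}\) with published defaults \(\lambda_{adv} = 1\),
\(\lambda_{ccl} = 5\), \(\lambda_{oml} = 10\).

Training uses Adam (\(\beta_1 = 0.5\), \(\beta_2 = 0.99\)) with the
learning rate decayed linearly to zero over the configured iteration count;
the full-scale preset is \(2\times 10^{-4}\) over 250,000 iterations at
batch 16 on 256×256 slices. The expectation \(E[\cdot]\) is realized as the
within-batch mean. One generator update and one discriminator update are
applied per iteration; the subject-level train/validation split is 8:2.

### Architecture

The printed source does not specify layer counts, so the architecture is
configuration-driven in the canonical residual-translator style: the
generator is a full-resolution stem → residual blocks → projection network
with a final sigmoid squashing outputs to \([0,1]\); the discriminator is a
strided 4×4 convolution stack emitting a patch logit map. Normalization
layers are not implemented (`norm = "none"`); at the CPU scales this
package targets they were not needed for stable training. No deep-learning
framework exists in the supported R stack, so convolution
forward/backward, backpropagation through the composed cycle graph, and
Adam are implemented in the package (C++ kernels via Rcpp/Armadillo);
gradients are verified against finite differences in the test suite.

### Desk-scale (CI) preset

`train_config_ci()` trains 8-filter/1-residual-block networks on 64×64
slices with batch 4 and a learning rate of \(10^{-3}\). The elevated rate
(versus the published \(2\times10^{-4}\)) is deliberate: the published rate
is coupled to a 250,000-iteration schedule, and at a few hundred iterations
it leaves the networks essentially untrained. With the CI preset a
1000-iteration run on one CPU lifts held-out harmonized-vs-baseline
volume-wise SSIM from about 0.73 (unharmonized) to about 0.87, restores
PSNR by about 3 dB, and reduces the mean per-region CNR difference — while
the `lambda_oml = 0` arm of the same run reconstructs BL→FU→BL visibly
worse than the `lambda_oml = 10` arm, the directional ablation result.
An identity-initialised residual generator variant was evaluated and
rejected during development: it learns the intensity map faster, but with
both generators anchored at the identity the plain cycle-consistent
baseline never drifts, so the ablation's direction — the very phenomenon
the original matching loss addresses — cannot be expressed at desk scale.

## Preprocessing

1. Resample to an isotropic cubic grid (full scale: 256³ at 1 mm), linear
   interpolation for intensities, nearest-neighbour for labels, field of
   view centred.
2. Min–max normalize each volume to \([0,1]\) at 32-bit precision,
   recording the original range; inference restores intensities through the
   exact inverse map.
3. Rigidly register the FU volume to its BL volume (6 degrees of freedom).
4. Split into axial slices and exclude the upper and lower 10%
   (`floor(0.1 N)` per end — 256 slices retain 206 at 0-based indices
   [25, 231)); pair retained slices by index.

The 10% exclusion is applied after resampling (the source is silent on the
order). During volume-level inference, excluded slices pass through
untransformed so the output grid and metadata equal the input.

## Rigid registration

The registration contract is *parameter recovery*: on phantoms with known
misalignment up to 5° and 5 voxels, the recovered transform must be within
0.5° and 0.5 voxels. The reference pipeline used an external tool with
default settings, which cannot be reproduced bit-exactly; this
implementation uses a 6-parameter coarse-to-fine search (Nelder–Mead per
pyramid level, quasi-Newton polish at full resolution) over an
intensity-similarity objective.

The objective required care, and the choices are worth recording:

- **Global NCC fails across scanner styles.** Normalized cross-correlation
  is only invariant to *affine* intensity maps; interscanner differences
  are general monotone maps (gamma, contrast compression). On phantoms,
  NCC's optimum was displaced by more than a degree.
- **Interpolation bias.** With trilinear interpolation, the warped image is
  sharpest when the transform is lattice-aligned; on images with weak
  internal structure this "sharpness bonus" pulls the optimum toward the
  identity. Pre-smoothing both volumes (default sd 1 voxel) damps but does
  not remove this.
- **The adopted default** is NCC on *rank-transformed* intensities
  (Spearman-style): invariant under any monotone intensity remapping while
  retaining NCC's smooth landscape. Plain NCC and histogram NMI remain
  available (`metric =`); NMI was rejected as a default because its
  histogram estimator has well-known grid-aligned artifacts at this volume
  size.

Worst-case recovery across the test battery (default phantom misalignment,
pure translations, single-axis 5° rotations, a combined 5°/5-voxel case) is
about 0.42° and 0.49 voxels.

## The phantom: a stated world

Each subject is procedural anatomy rendered under two scanner styles:

- **Geometry**: a GM-like head ellipsoid containing a WM-like core and two
  CSF-like ventricles; `n_regions` seeded spherical subregions (standing in
  for a parcellation); a spherical enhancing lesion whose radius can change
  between visits. The GM and WM boundaries carry seeded angular ripples
  (folding), and tissue intensity is modulated by a seeded anatomy-frame
  texture (sum of plane waves at roughly gyral-to-lobar wavelengths).
  Neither flourish is cosmetic: a piecewise-constant near-ellipsoidal
  phantom is almost rotation-symmetric to any intensity-based registration,
  and sub-degree parameter recovery would be meaningless on it.
- **Styles**: per-tissue mean intensities, a gamma exponent, a multiplicative
  degree-2 polynomial bias field, a Gaussian point-spread function (sd 0.6
  voxels, band-limiting the render as a real acquisition does), and
  additive Gaussian noise. Style A (baseline scanner): full contrast, flat
  bias, noise sd 0.01. Style B (follow-up scanner): compressed contrast
  (WM 0.55 vs 0.70), gamma 0.8, a bias field of roughly ±10% across the
  head, noise sd 0.015. The real interscanner difference is not quantified
  publicly, so these magnitudes are package choices, fixed once: large
  enough that BL/FU pairs are visibly mismatched (volume-wise SSIM about
  0.7 on 64³ phantoms) and histogram matching alone cannot fully repair
  them (the bias field is spatially varying).
- **Misalignment**: the follow-up is generated *analytically in the
  misaligned pose* — the grid point is pulled back through the rigid
  transform before the geometry is evaluated — rather than by resampling a
  rendered volume. This keeps generated data free of interpolation blur,
  which would otherwise contaminate the registration-recovery contract the
  phantom exists to test. The default misalignment is 1.5°/−1°/0.5°
  rotations and 2/−1.5/1 voxel translations, modest values typical of
  repositioning between visits.
- **Noise model**: Gaussian, not Rician. At the moderate SNRs and
  normalized intensities simulated here the difference is small; this is a
  documented limitation.

Determinism: a spec plus seed reproduces every volume bit-for-bit; all
randomness flows through seeds derived from the subject seed.

What a green phantom test does *not* establish: performance on real
contrast-enhanced tumour MRI, robustness to motion/susceptibility
artifacts, skull and scalp intensity structure, or the behaviour of the
published full-scale model. Phantom results are directional, not clinical.

## Metrics

- **SSIM** with stabilization constants \(c_1 = (0.01L)^2\),
  \(c_2 = (0.03L)^2\) and an 11-point Gaussian window (sd 1.5) in sliding
  mode (the reference-standard defaults; the source prints the formula but
  not the constants). Sliding statistics are computed over fully interior
  windows; global mode uses whole-image moments. Volume-wise evaluation
  uses a 3D sliding window; slice-wise evaluation computes per-slice values
  and aggregates.
- **PSNR** \(= 10\log_{10}(L^2/\mathrm{MSE})\); for normalized inputs
  (L = 1) this coincides with the printed \(10\log_{10}(L/\mathrm{MSE})\).
  Identical images yield an `Inf` sentinel, excluded from aggregation.
- **LPIPS** is interface-only: the printed layer-weighted squared feature
  distance over an *injected* extractor. Parity with published perceptual
  weights is out of scope; `test_feature_extractor()` provides a
  deterministic two-layer extractor for plumbing and tests.
- **CNR** \(= (\mu_{ROI} - \mu_{bg})/\sigma_{bg}\) with the population
  standard deviation. The source does not define its background region; the
  background mask is caller-supplied, and on phantoms the ground-truth
  background is used.
- **Dice**; two empty masks are defined as Dice 1.
- **Average Hausdorff distance**: the symmetric mean of the two directed
  mean nearest-boundary-voxel distances in physical units (face-adjacency
  boundary, array edges count as outside); classical max-Hausdorff is an
  option.

Aggregation of slice-wise tables is reported both pooled and per subject
(the source is silent on which it used).

## Statistics

`wilcoxon_signed_rank()` drops zero differences, mid-ranks ties, uses the
exact permutation null (over sign assignments of the observed ranks) up to
n = 25 and a tie- and continuity-corrected normal approximation beyond;
`paired_t_test()` is the standard two-sided paired t. Both are validated
against brute-force enumeration and the independent reference
implementations in base R. No multiple-testing correction is applied (raw
p-values at α = 0.05, as in the source analysis).

## Numerical choices and degenerate inputs

- Min–max normalization is per-volume with no percentile clipping (the
  stated preprocessing is a plain linear map); constant volumes are
  rejected rather than silently scaled.
- Histogram matching uses 256-bin quantile mapping over above-zero voxels;
  exactly-zero voxels pass through.
- Adversarial logs are clamped at 10⁻⁷; discriminator scores are treated as
  logits (whether the published discriminators were sigmoid-activated
  before the loss is not printed — treating scores as logits makes the
  clamped log form well defined).
- All slice indices are 0-based half-open ranges; the axial axis is the
  third array axis.
- Checkpoints are versioned RDS archives (weights, specs, loss weights,
  iteration, seed) supporting resumption with a continuing iteration
  counter.

## Known limitations

- CPU-scale networks only; no GPU path, mixed precision or distribution.
- Gaussian noise model; no Rician floor, motion, or susceptibility effects.
- LPIPS values are not comparable to published LPIPS numbers.
- Instance/batch normalization is not implemented.
- The phantom's scanner-style magnitudes are plausible but uncalibrated —
  the corresponding clinical effect sizes are unavailable by construction.
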