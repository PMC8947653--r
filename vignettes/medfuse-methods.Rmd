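---
title: "Hybrid CT/MRI fusion: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid CT/MRI fusion: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medfuse)
```

## The problem

CT and MRI image complementary anatomy: CT renders bone and implants with
high contrast but little soft-tissue detail, MRI the reverse. Given two
co-registered single-slice images, the pipeline produces one image that
retains the salient content of both. Inputs are assumed well aligned; no
registration is attempted. Real acquisitions also carry non-uniform
illumination and sensor noise, which the preprocessing stage addresses
before any fusion decision is made.

## Pipeline and assumptions

### Morphological preprocessing

With a flat structuring element `b`, the bottom-hat residue
`W_b = closing(f, b) − f` collects dark artifacts and the top-hat residue
`W_w = f − opening(f, b)` collects bright detail, both at scales smaller
than `b`. Two combinations are provided:

* `classic` (default): `clip(f + W_w − W_b, 0, 1)` — the standard
  contrast-enhancement identity; bright features are boosted and dark
  artifacts suppressed while the base image is retained.
* `paper_literal`: `clip(W_w − W_b, 0, 1)` — the bare residue difference.
  This variant discards the base image and with it the large-scale
  illumination field, so it is the one that literally flattens a ramped
  background; the cost is that all content at scales above `b` is lost.

The default is `classic` because a fusion pipeline needs the anatomy, not
only the residues. The element is a disk of radius 9 px for 256-px images,
scaled proportionally (minimum 3): it must exceed the noise/texture scale
but stay below anatomy scale. Erosion/dilation are delegated to EBImage and
computed on a mirror-padded domain (pad = 2·radius) so clipped anatomy does
not generate border residues; unit tests verify exact agreement with a
brute-force window min/max oracle.

### Gray-PCA decolorization

RGB inputs are converted to YCbCr (ITU-R BT.601 full range — declared so
results are bit-stable), each channel zero-meaned, and a PCA taken over the
3-vector pixel population. The output is the combination of all three
eigenprojections with weights `√λ_k / Σ √λ`, min-max rescaled to [0, 1].
Weight and sign conventions are design choices (nothing in the method fixes
them): √λ weighting retains chroma detail in proportion to its standard
deviation, and each eigenvector's sign is fixed by positive correlation
with luminance (falling back to the sign of its largest component), making
the output deterministic even though eigenvector signs are arbitrary.
Degenerate cases: an R=G=B image reduces exactly to its rescaled common
channel; a constant image returns its constant luminance rather than
raising an error. Gray inputs bypass the stage entirely.

### The shift-invariant shearlet stage

Both requirements that motivate the transform — no blocking artifacts and
stability of fusion decisions under small shifts — come from one property:
every operation is a pointwise multiplication in the DFT domain, so the
whole analysis/synthesis commutes exactly with circular shifts and all
bands are image-sized.

*Multiscale split.* An undecimated à-trous pyramid uses the B3-spline
low-pass, per axis `H(ω) = ((1 + cos ω)/2)²` dilated by `2^(s−1)` at scale
`s`, with high-pass spectrum `K = √(1 − H²)`. This makes the pyramid a
tight frame: `|F_s|² = |F_{s+1}|² + |G_s|²` pointwise, band energies sum
exactly to the image energy, and the synthesis `F_s = H F_{s+1} + K G_s` is
the adjoint of the analysis. A plain additive-residual pyramid
(`g = f − f*h`, synthesis by summation) was rejected: it reconstructs
perfectly but its band energies sum to *less* than the image energy, which
defeats the energy-accounting invariant we test.

*Directional localization.* Wedge windows are Meyer bumps in the
pseudo-polar slope coordinate (`η = ξ₂/ξ₁` on the horizontal cone,
`2 − ξ₁/ξ₂` on the vertical, period 4), with `D` wedges per scale centered
at `η_d = 4(d−1)/D`. The Meyer pair identity makes the squared windows sum
to exactly 1 at every nonzero frequency; the DC sample is assigned wholly
to the first wedge. One genuinely numerical subtlety: on even-sized grids
the Nyquist row/column samples are their own Hermitian partners, where the
slope coordinate is not symmetric under frequency negation. Each window is
therefore symmetrized under the pairing `k → (n − k) mod n` and the
partition of unity renormalized — an identity everywhere except on those
lines. Without this step, taking the real part of filtered bands loses
energy on the Nyquist lines and round-trip error rises from ~1e−15 to
~1e−2.

Defaults: 3 scales, (8, 8, 16) directions coarse→fine — conventional
shearlet settings, config-exposed; direction counts must be powers of two.
Boundary handling is periodic (FFT-native), which is what makes the
shift-equivariance test exact.

### High-pass fusion

A two-branch shared-weight convolutional classifier decides, per 16×16
block pair, which source is clearer. The architecture is fixed (64, 128,
256 filters of 3×3/stride 1; one 2×2/stride-2 max-pool after the second
convolution; 256 features per branch from a 4×4 average pool; concatenated
512-vector into a 2-way soft-max; no fully connected layers), so the same
weights score a 16×16 patch (one output unit) or a whole band (a dense
stride-2 map whose units have 16×16 receptive fields). Implementation is
plain im2col + BLAS GEMM with small compiled gather/scatter kernels; no
deep-learning framework is involved.

Training data are synthetic (sharp crop, Gaussian-blurred copy) pairs in
random order with a per-pair fair coin — the published method does not
describe its corpus, so this generator is a stated stand-in that makes the
"which input is sharper" task learnable and label-balanced. Optimization is
SGD with batch 128, momentum 0.9, weight decay 1e−5; learning rate 0.01
and 10 epochs are package defaults (nothing in the method fixes them) and
an 80/20 split reports held-out accuracy. Everything (initialization,
shuffling, patch generation) derives from one seed, so two runs agree to
the last bit.

Per band pair the procedure is: normalize both bands to [0, 1] by
`(x − min)/(max − min + 1e−12)` (coefficients are signed and unbounded;
the classifier was trained on [0, 1] patches); score densely and
redistribute each block score over its 16×16 source block, dividing by
coverage; threshold strictly at 0.5; majority-vote over a truncated 8×8
window (even window, the extra rows/columns toward lower indices; an exact
tie keeps the pixel — deterministic and minimal-intervention); refine with
a guided filter (r = 4, ε = 0.1) whose guide is the preprocessed first
source image — an intensity guide supplies edges, while the near-zero-mean
band itself would not; and composite raw coefficients as
`F_h = Dm·C_h + (1 − Dm)·D_h`. Decision maps are computed per band
(`map_scope = "per_band"`), preserving directional selectivity; a
per-scale variant (scores averaged over a scale's directions) is available
for speed.

### Low-pass fusion

Local energy over a 3×3 all-ones template (only the size is prescribed;
normalization cancels in every comparison the rule makes) and the salience
factor `S = 2 Σ W_c L_C L_D / (En_C + En_D)` gate the rule: averaging with
weights α_max = 0.7 / α_min = 0.3 when `S > 0.5` (the correlated case;
the milder majority weighting implements "averaging" without collapsing
into selection), otherwise selection of the higher-energy coefficient.
The template weight appears in the salience numerator as well as the
energies so that identical bands give S = 1 exactly. Where both window
energies vanish (< 1e−12) the bands are identically null and S is defined
as 1, routing the (zero) coefficients through averaging rather than
dividing by zero. Energy ties select the first input — the inequalities
are taken exactly as written (`En_C ≥ En_D`). Borders mirror-pad,
consistently with the energy window.

### Reconstruction and display

The fused pyramid is inverted by the adjoint transform. The raw
reconstruction is real-valued and can leave [0, 1] slightly, so the
default display normalization is an affine min-max rescale (`clip` is
available). Metrics are computed against the preprocessed gray sources —
the images the fusion actually consumed; comparing against raw inputs
would mix preprocessing quality into a fusion metric.

## Quality metrics

The four reported measures follow the edge-information-preservation
framework: Sobel strength `g` and orientation `α` per image; relative
strength `G = min(g_X, g_F)/max(g_X, g_F)` and orientation agreement
`A = 1 − Δα/(π/2)` (Δα wrapped to [0, π/2]); sigmoid scores
`Q_g = Γ_g/(1 + e^{k_g(G − σ_g)})`, `Q_α` likewise; `Q^{XF} = Q_g Q_α`
weighted by source edge strength. Constants default to k_g = −10,
σ_g = 0.5, k_α = −20, σ_α = 0.75 and are config-exposed. The Γ factors are
chosen so that a perfectly preserved edge scores exactly 1 — with the
classical constants a perfect fusion scores ≈ 0.99, which would make the
identity `QFAB(A, A, A) = 1` hold only approximately; the normalization
changes nothing about the ordering of methods. NFAB accumulates the
unpreserved weighted information at artifact locations (fused edge
strictly stronger than both source edges); CRR is the mean of the two
Pearson correlations; AG is the mean forward-difference gradient magnitude
`mean √((∂x F² + ∂y F²)/2)`.

Two observations worth recording. A period-1 checkerboard is invisible to
Sobel operators (the [1,2,1] smoothing nulls Nyquist), so artifact tests
inject block-structured noise instead. And a pixelwise-average fusion can
essentially never trigger the artifact condition on its own scale — the
average of two gradients cannot exceed both — so NFAB comparisons between
an averaging baseline and any decision-map method are only meaningful when
both outputs are brought to the same display normalization, and even then
averaging is close to a lower bound for this measure (see Limitations).

## The synthetic phantoms

`generate_phantom_pair()` emulates the structure that makes CT/MRI fusion
interesting rather than any acquisition physics: one shared anatomy (an
elliptical skull ring plus 3–5 random interior blobs) rendered twice —
bright ring/dark interior with faint blobs for CT, dark ring/bright
textured interior for MRI (band-limited Gaussian texture, correlation
length 2.5 px). Both are multiplied by a low-order polynomial illumination
ramp (amplitude `illum_strength`, mirrored between modalities, analytic
mean exactly 1) and corrupted by additive Gaussian noise, then clipped.
Defaults — 128 px, noise SD 0.02, illumination amplitude 0.3 — are the
package's stated evaluation conditions: visible but not dominant
degradation at a size where the full pipeline runs in seconds. The
generators are pure functions of their arguments, and the two modality
masks are shared, so fusion tests know exactly which pixels are bone and
which are tissue.

What the phantoms do *not* emulate: modality-specific noise statistics
(Rician MRI noise, CT streaking), partial-volume effects, misregistration,
3-D context, and pathology. Passing tests on phantoms therefore shows the
machinery is correct and the fusion rules behave as designed — not that
clinical image quality matches any published figure on real datasets.

## Numerical choices and degenerate inputs

* Round-trip, shift-equivariance and partition-of-unity hold to ~1e−15,
  ~1e−16 and ~1e−16; tests assert the method-level tolerances 1e−4 / 1e−6.
* Guided filter and box means use border-truncated windows (count
  normalization), matching the common integral-image formulation; at very
  large ε the output tends to the box mean applied twice (the `mean_a·I +
  mean_b` structure), which is the closed form the limit test asserts.
* `initial_segment` thresholds strictly (`M > 0.5`); a score of exactly
  0.5 maps to 0.
* Score redistribution divides by per-pixel coverage; on odd-sized inputs
  a thin uncovered border replicates the nearest covered row/column.
* Max-pool gradient ties route to the first candidate in scan order;
  training is bit-deterministic under its seed.
* Constant images: hats are zero, enhancement is the identity, high bands
  vanish, the low band is the constant; metrics that would divide by zero
  (correlation or edge weights of constant images) raise errors rather
  than returning NaN.

## Problem sizes used in the checks

The shipped checks run at the sizes the method is specified at: 128×128
images with 3 scales and (8, 8, 16) directions for transform and pipeline
properties; 5000 patch pairs / 10 epochs for classifier training; ten
seeded phantom pairs for the pipeline-versus-baseline comparison; oracle
equivalences on 8×8–32×32 inputs where brute-force references are exact.

## Known limitations

* The artifact measure structurally favors averaging: a decision-map
  method necessarily creates some sourceless edge energy where the
  decision map transitions (`∇Dm·(C_h − D_h)` terms), while an averaging
  baseline cannot exceed both source gradients. On these phantoms the
  pipeline clearly wins edge transfer (QFAB, every pair) but does not beat
  the averaging baseline on NFAB; expecting both simultaneously against
  *this* baseline appears unattainable for any method of this family, as
  opposed to the published comparisons against transform-domain baselines,
  which do show lower NFAB for the decision-map method.
* Training patches are blur-discriminative only; the classifier transfers
  to shearlet bands through the [0, 1] normalization but has never seen
  signed band statistics during training.
* The transform's periodic boundary trades border fidelity for exact
  shift-equivariance; symmetric pre-padding is the usual remedy if border
  content matters.
* Single 2-D slices only; no DICOM, no volumes, no registration.
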