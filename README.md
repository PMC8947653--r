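# medfuse

Hybrid CT/MRI medical image fusion in R.

CT shows bone and implants; MRI shows soft tissue. Fusing two co-registered
slices into one image gives a clinician both kinds of information at once.
`medfuse` implements a complete decision-map fusion pipeline for such pairs:

1. **Morphological preprocessing.** Bottom-hat `W_b = (f • b) − f` and
   top-hat `W_w = f − (f ∘ b)` residues over a flat disk `b` correct
   non-uniform illumination and suppress background noise; the default
   enhancement is `clip(f + W_w − W_b, 0, 1)`.
2. **Gray-PCA decolorization.** RGB inputs are mapped to zero-mean YCbCr,
   a PCA over the 3-vector pixel population is taken, and the gray image is
   the √λ-weighted combination of the three eigenprojections.
3. **Local shift-invariant shearlet transform (LSIST).** An undecimated
   tight-frame pyramid (B3-spline low-pass `H`, high-pass `K = √(1 − H²)`)
   splits each image into one low-pass band and, per scale, Meyer-window
   directional wedges on the pseudo-polar grid (defaults: 3 scales with
   8, 8, 16 directions). Every band is image-sized; the squared directional
   windows sum to 1, so reconstruction is exact to machine precision and
   sub-bands commute with circular shifts.
4. **High-pass fusion by a Siamese CNN.** A two-branch shared-weight
   classifier (conv 64 → conv 128 → 2×2/2 max-pool → conv 256, 3×3 kernels,
   stride 1, 512 concatenated features, 2-way soft-max) is trained on
   synthetic sharp/blurred 16×16 patch pairs with SGD (batch 128, momentum
   0.9, weight decay 1e-5). Applied fully convolutionally to each band pair
   it yields a score map `M`; `B = 1{M > 0.5}`, an 8×8 majority vote removes
   singularities, a guided filter (r = 4, ε = 0.1) refines the map to `Dm`,
   and bands composite as `F_h = Dm·C_h + (1 − Dm)·D_h`.
5. **Low-pass fusion by local energy.** With 3×3 template `W_c`, local
   energy `En = Σ L² W_c` and salience `S = 2 Σ L_C L_D W_c / (En_C + En_D)`
   gate averaging (`S > T = 0.5`, weights α_max/α_min for the
   higher/lower-energy band) versus selection of the higher-energy
   coefficient.
6. **Reconstruction and metrics.** The inverse transform and min-max display
   normalization produce the fused image; quality is reported as edge
   transfer QFAB, mean source correlation CRR, average gradient AG, and the
   fused-edge artifact measure NFAB.

Deterministic synthetic generators (CT-like/MRI-like head phantoms sharing
one anatomy, plus labeled sharp/blurred training patches) make every stage
testable offline — no image downloads are required anywhere.

## Worked example

```r
library(medfuse)

pair <- generate_phantom_pair(size = 128, noise_sd = 0.02,
                              illum_strength = 0.3, seed = 1)
patches <- generate_patch_pairs(5000, 16, c(1, 3), seed = 1)
net <- train_network(patches, network_config(epochs = 10, seed = 11))
net$training$holdout_accuracy
#> [1] 1

res <- fuse_images(pair$ct, pair$mri, net)
str(res$metrics)
#> List of 4
#>  $ qfab: num 0.584
#>  $ crr : num 0.674
#>  $ ag  : num 0.0719
#>  $ nfab: num 0.0348
write_image(res$fused, "fused.png")
```

QFAB near 0.58 means well over half of the weighted source edge information
survives into the fused image (a plain pixel average of the same
preprocessed sources reaches about 0.47 on this pair); CRR 0.67 is the
mean correlation with the two sources; AG is the mean gradient magnitude
(sharpness, here on a [0,1] intensity scale); NFAB 0.03 means only ~3% of
the weighted edge information is "sourceless" artifact content. Higher
QFAB/CRR/AG and lower NFAB are better.

A thin command-line tool wraps the same functions:

```sh
medfuse phantom --out-dir d --size 128 --seed 7
medfuse train --out net.rds --n-patches 5000 --epochs 10 --seed 1
medfuse fuse --a d/ct.png --b d/mri.png --out fused.png --weights net.rds
medfuse eval --a d/ct.png --b d/mri.png --f fused.png
```

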