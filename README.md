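# daasr — reference-guided MRI super-resolution with dual attention aggregation

`daasr` reconstructs a high-resolution (HR) 2D MRI slice from a
low-resolution (LR) input *and* an HR reference slice from the same
acquisition domain. It is aimed at researchers studying reference-based
super-resolution (RefSR) mechanisms for medical images: every component is
an ordinary R function over matrices/arrays, trainable and inspectable on a
laptop CPU, with synthetic brain phantoms standing in for clinical data so
the whole pipeline runs without downloads.

## The model

The network stacks Hierarchical Feature Alignment Groups (HFAGs). Each
group combines a structural branch and a texture-transfer branch with
residual aggregation:

    F_CWT = CWT(F_in)
    F_SAT = SAT(F_CWT, F_Ref, F_Ref↑↓)
    F_out = F_CWT + F_SAT + F_in

- **CWT (channel-wise transformer).** Q/K/V are C×C linear projections of
  the flattened (HW)×C feature map, transposed so attention is a C×C map
  over *channels*: `A = softmax(Q_C K_Cᵀ)`, output `A·V_C` restored to the
  spatial layout, inside a pre-norm LN–CWT–LN–MLP block. This models global
  inter-channel structure rather than local pixel correlations.
- **SFE (spatial feature extractor).** A small learnable encoder (3×3 conv
  + ReLU + three conv–BN–ReLU residual blocks), applied with shared weights
  to the reference `I_Ref` and its bicubically blurred copy `I_Ref↑↓`.
- **SAT (spatial alignment transformer).** Patch-level cosine similarity
  `M[i,j] = ⟨q_i/‖q_i‖, k_j/‖k_j‖⟩` between query patches (from the
  structural features) and blurred-reference key patches yields a hard
  **index map** `P[i] = argmax_j M[i,j]` and a **score map**
  `C[i] = max_j M[i,j]`. The indexed value patches are retrieved from the
  sharp reference features, folded back with overlap averaging,
  concatenated with `F_CWT`, fused by a 1×1 convolution and modulated by
  the confidence: `F_SAT = Conv([F_CWT, (V_S)_P]) ⊙ C`.
- **Reconstruction.** Sub-pixel (pixel-shuffle) heads decode the final
  features — and, for auxiliary supervision, the last stage's branch
  outputs — into images at scale ×2/×3/×4, on top of a global bicubic skip.

Training minimises the hierarchical objective
`L = λ₁‖I_SR − I_HR‖₁ + λ₂ L_CWT + λ₃ L_SAT` with λ₁ = 1, λ₂ = 0.1,
λ₃ = 0.01, where `L_SAT` adds a perceptual distance (weight λ_p = 0.1)
computed by a frozen feature extractor. Evaluation uses PSNR
(`10·log10(MAX²/MSE)`) and SSIM with border cropping. All network layers
run on a compact reverse-mode autodiff engine included in the package —
no external deep-learning framework.

## Worked example

```r
library(daasr)

## two synthetic brain slices: one target, one reference
hr  <- generate_phantom(phantom_params(size = 64, seed = 1))
ref <- generate_phantom(phantom_params(size = 64, seed = 2))

## x2 degradation: LR input + blurred reference key copy
sample <- make_training_sample(hr, ref, scale = 2)
dim(sample$lr)
#> [1] 32 32

## bicubic baseline against the ground truth
up <- bicubic_resize(sample$lr, 64, 64)
round(c(psnr_db = psnr(up, hr, border = 2),
        ssim = ssim(up, hr, border = 2)), 3)
#> psnr_db    ssim
#>  20.079   0.835

## hard patch matching: confidence of the best reference match per query
sfe <- init_sfe_params(16, seed = 3)
q <- extract_spatial_features(bicubic_resize(sample$lr, 64, 64), sfe)
k <- extract_spatial_features(sample$ref_blurred, sfe)
m <- hard_match(similarity_matrix(patchify(q, 3, 2), patchify(k, 3, 2)))
round(summary(m$score_map), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.950   0.995   0.999   0.996   1.000   1.000

## forward pass of a (still untrained) model
model <- init_daasr(daasr_config(channels = 16, n_hfag = 2, scale = 2))
out <- daasr_forward(sample$lr, sample$ref, sample$ref_blurred, model)
dim(out$i_sr)
#> [1] 64 64
```

The bicubic upsampling reaches 20.1 dB on this phantom; `m$score_map` shows
that nearly every LR patch finds a high-confidence (cosine ≈ 1) match in
the blurred reference — the signal the alignment transformer transfers
texture along. Training a model is one call:

```r
fit <- train_daasr(train_config("desk", seed = 1), verbose = TRUE)
sr  <- super_resolve(sample$lr, sample$ref, fit$model)
```

The `"desk"` profile (16 channels, 2 HFAGs, 32 phantoms of 64×64 at ×2,
20 epochs) trains in about 4 minutes on one CPU and clears the bicubic
baseline by ≈ 3.7 dB on its held-out split; `train_config("full")` records
the full-scale settings (64 channels, 6 HFAGs, 200 epochs, batch 9,
lr 2e-4 halved every 20 epochs).

A command-line wrapper is included at `inst/cli/daasr.R`
(`generate-data`, `train`, `super-resolve`, `eval`), e.g.

```sh
Rscript inst/cli/daasr.R generate-data --n-slices 16 --size 64 --scale 2 --seed 1 --out-dir data/
```

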