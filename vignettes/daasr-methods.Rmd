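---
title: "Reference-guided MRI super-resolution: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided MRI super-resolution: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-image MRI super-resolution is limited by the information in the
low-resolution (LR) slice: at larger scale factors the high-frequency
anatomy simply is not there. In many MRI workflows, however, a
high-resolution (HR) *reference* slice from the same acquisition domain is
available — another subject scanned under the same protocol, an adjacent
slice, a different contrast. Reference-guided super-resolution (RefSR)
conditions the reconstruction on such a reference, with the central risk
that a misused reference injects anatomically wrong detail. `daasr`
implements a dual-attention RefSR network that separates *structural
modelling* of the LR input from *controlled texture transfer* out of the
reference, so unreliable transfers are down-weighted rather than pasted in.

## Model

The network is a stack of `n_hfag` hierarchical feature alignment groups
(HFAGs). Given working-grid features $F_{in}$, each group computes

$$F_{CWT} = \mathrm{CWT}(F_{in}), \qquad
  F_{SAT} = \mathrm{SAT}(F_{CWT}, F_{Ref}, F_{Ref\uparrow\downarrow}),
  \qquad
  F_{out} = F_{CWT} + F_{SAT} + F_{in}.$$

**Channel-wise transformer (CWT).** The (HW)×C feature matrix is projected
by learnable C×C matrices and transposed, so attention is computed between
*channels*: a C×C map `softmax(Q_C K_C^T)` captures global inter-channel
dependencies rather than local pixel correlations. The block is the
pre-norm sequence LN–CWT–LN–MLP with residual connections. Following the
formulation literally, the logits carry no $1/\sqrt{d}$ scaling; a
configurable temperature is exposed instead, and training-time stability is
guarded by global-norm gradient clipping (1.0). Layer normalisation acts
per spatial position over channels (the alternative reading — per channel
over positions — would make the block non-equivariant to spatial
permutations, a property the channel-domain design otherwise has and which
the test suite asserts). The MLP uses expansion ratio 2 with GELU; single
attention head; default C = 64.

**Spatial feature extractor (SFE).** A deliberately small learnable
encoder — one 3×3 convolution + ReLU and exactly three residual blocks
(conv–BN–ReLU twice, identity skip) — applied with *shared weights* to the
reference $I_{Ref}$ and its blurred copy $I_{Ref\uparrow\downarrow}$
(bicubic down/up resampling). No pretrained features are used anywhere in
the extractor: fixed classification features transfer poorly to low-level
MRI texture, and a task-trained encoder adapts to the acquisition domain.

**Spatial alignment transformer (SAT).** Queries are the structural
features projected by a learnable C×C matrix; keys are SFE features of the
blurred reference; values are SFE features of the sharp reference. All
three are cut into p×p patches (default p = 3, stride 1 on the feature
grid — dense matching; `sat_patch_size`/`sat_stride` reproduce coarser
settings). Cosine similarity between query and key patches gives an N×M
matrix; per query patch, the *index map* P is the argmax (hard retrieval,
ties to the smallest index) and the *score map* C the attained maximum.
The retrieved value patches are folded back with overlap averaging,
concatenated with $F_{CWT}$, fused by a 1×1 convolution and multiplied by
the score map broadcast to pixels through the same fold. Hard retrieval
avoids the blur of soft averaging; the soft comparator is retained as the
`disable_index_map` ablation.

**Reconstruction heads.** Sub-pixel convolution (pixel shuffle; one stage
for ×2/×3, two ×2 stages for ×4) followed by a 3×3 convolution to one
channel. A global bicubic skip of the LR input is added so each head
predicts a residual; the final 1-channel convolution is initialised at
0.01× its fan-in scale so the initial prediction sits at the interpolation
baseline while every parameter still receives gradient. The same head
architecture (separate weights) reconstructs $I_{SR}$ from the last
$F_{out}$ and the auxiliary images $I_{CWT}$, $I_{SAT}$ from the last
stage's branch outputs. The bicubic skip and the small head initialisation
are this package's additions (configurable off via `global_skip`): without
them the auxiliary image heads under-constrain early training.

## Working grid

The formulation upsamples structural features before alignment and sums
branch outputs at one resolution, which is shape-inconsistent if alignment
runs on the HR grid while aggregation runs on the LR grid. The default here
brings *reference* features down instead: the SFE head convolution uses
stride = scale, so matching, fusion and aggregation all live on the LR
feature grid (cheaper, shape-consistent). The literal alternative —
upsample the query, match at HR, pool the result back — is available via
`sat_grid: "hr"`.

## Differentiability of the matcher

The argmax defining P is discrete and carries no gradient. The confidence
$c_i = \max_j M_{ij}$ *is* differentiable almost everywhere and enters the
output multiplicatively, so it is kept on the autodiff tape via the
selected normalized-patch inner products: gradients flow into both the
query and key encoders. The full N×M similarity matrix is needed only for
the argmax and is computed off-tape. In the soft-attention ablation the
softmax weights are treated as constants.

## Losses

With $\lambda_1 = 1$, $\lambda_2 = 10^{-1}$, $\lambda_3 = 10^{-2}$:

$$L = \lambda_1 \lVert I_{SR} - I_{HR}\rVert_1
    + \lambda_2 \underbrace{\lVert I_{CWT} - I_{HR}\rVert_1}_{L_{CWT}}
    + \lambda_3 \underbrace{\big(\lVert I_{SAT} - I_{HR}\rVert_1
    + \lambda_p \lVert \phi(I_{SAT}) - \phi(I_{HR})\rVert_2^2\big)}_{L_{SAT}},
  \qquad \lambda_p = 10^{-1}.$$

As stated, the texture term references $\phi(I_{CWT})$ inside $L_{SAT}$; this
package reads that as a typo for $\phi(I_{SAT})$ (the term supervises the
texture branch) and keeps the literal variant behind
`loss$perceptual_on = "cwt"`. The perceptual distance is a *mean* (not sum)
of squared feature differences so $\lambda_p$ is resolution-independent.
The extractor $\phi$ is frozen; the packaged default is a seeded
multi-scale random convolutional feature stack (`kind = "rand_conv"`),
which is deterministic, download-free and sufficient as a high-frequency
regulariser; a pretrained VGG-19 relu3_3 extractor is the intended
full-scale choice but requires external weights, so requesting it errors
with guidance. An optional non-saturating patch-GAN term (weight
$\lambda_{adv} = 10^{-3}$, off by default — the core objective has no
adversarial component) is provided for completeness.

## Training data and degradation

HR slices are bicubically downsampled (Keys kernel $a=-0.5$, kernel
widening on decimation for antialiasing) by scale 2, 3 or 4; slices whose
sides are not multiples of the scale are centre-cropped first. Each LR
input is paired with a reference drawn from the *same* train/val/test split
(70/15/15 by seeded shuffle), never across splits. The blurred reference
key copy is degraded by the *training scale* by default — matching the
degradation level of query and key is the stated purpose of the blurred
copy — while a fixed factor of 4 (the literal reading) is available via
`ref_blur_factor = 4`. "Down then up" is implemented as
downsample-by-factor followed by upsample-to-original, the only order that
removes high frequencies. Augmentation draws one of the eight dihedral
transforms per sample per epoch and applies it to LR, HR, reference and
blurred reference alike.

## The synthetic phantom generator

`generate_phantom()` emulates what matters to this architecture in an
axial brain slice: five nested tissue regions (background, bright skull
ring, dark CSF gap, mid-gray cortical ribbon, brighter white-matter core)
bounded by a randomly deformed ellipse (low-order Fourier modes of the
radius), plus ridge-like sulcal texture confined to the cortical ribbon —
the high-frequency content the texture-transfer branch exists for —
and optional Gaussian or Rician noise (default none: the degradation model
is clean bicubic downsampling). It is a pure function of its parameters.
What it does *not* emulate: scanner bias fields, partial-volume effects,
coil-noise correlation, pathology, and true anatomical variability; passing
tests on phantoms demonstrates that the mechanisms work as specified, not
clinical-grade reconstruction quality.

## Scaled-down study conditions

The full-scale profile (recorded as `train_config("full")`) uses C = 64,
six HFAGs, 200 epochs at batch 9, lr 2e-4 halved every 20 epochs, on
256×256 slices. The tested `"desk"` profile — the configuration every
result in this repository is computed under — uses C = 16, two HFAGs,
32 phantoms of 64×64 at ×2, 20 epochs. Its optimizer settings are the
package's own choices for that size: lr 2e-3 (a small model tolerates and
needs a larger step within 20 epochs), batch 2 (more optimizer steps per
epoch on 22 training slices), the same halve-every-20 step decay, Adam
β₁ = 0.9 / β₂ = 0.999, global-norm clipping at 1.0. Under seed 1 this run
takes about 4 minutes on one CPU and reaches a held-out PSNR roughly 3.7 dB
above the bicubic baseline (the acceptance script recomputes this from
scratch).

## Evaluation

PSNR = $10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$ with MAX = 1 on
per-slice min-max normalised intensities; identical images report an
infinite PSNR which dataset means exclude with a warning. SSIM is provided
in the literal *global* form (whole-image moments) and the
conventional *local* form (11×11 Gaussian window, σ = 1.5, valid support,
averaged; k₁ = 0.01, k₂ = 0.03), the default reported metric. Borders are
cropped before evaluation; the width is scale pixels per side
(scale-proportional cropping is the community convention; the amount is
otherwise unspecified). Metrics are computed per slice and averaged.

## Numerical and design notes

- **Autodiff engine.** No deep-learning framework is involved: layers run
  on a compact reverse-mode engine included in the package. Convolution is
  one precomputed index gather (reflection padding folded into the same
  index) plus a BLAS matmul; its adjoint is a `rowsum()` scatter. Every op
  is gradient-checked against central finite differences in the test suite.
- **Residual aggregation algebra.** With branch internals zeroed, the CWT
  block reduces to the identity and SAT to zero, so the aggregation rule
  yields exactly $2^k F_{in}$ after k groups (asserted in tests). With a
  branch *disabled*, the aggregation drops the corresponding term
  (`use_sat = FALSE` gives $F_{CWT} + F_{in}$; disabling both gives the
  identity) rather than double-counting the input.
- **Zero-norm patches.** Cosine similarity is defined as 0 when either
  operand has zero norm: neutral (never beats a positive match) and
  deterministic.
- **Ties** in hard matching break to the smallest key index.
- **Score-map broadcast.** The per-patch confidence is spread uniformly
  over the patch footprint and overlap-averaged — the same fold used for
  retrieved patches.
- **Reference features are computed once** per forward pass and shared by
  all groups; recomputation would be weight-identical.
- **BN statistics** use momentum 0.1 and are part of the checkpoint;
  save/load round-trips bit-exactly, including optimizer and RNG state, so
  interrupted training resumes to bit-identical results.
- **Auxiliary heads** attach to the *last* group's branch outputs (the
  supervision stage is unstated; per-stage supervision is available via
  `per_stage_supervision`). The auxiliary heads use separate weights from
  the main head.
- **Scale 3** uses one 3× sub-pixel stage; scale 4 stacks two 2× stages.
- **Ablation tags** (`run_ablation`): `full`, `no_cwt`, `no_sat`,
  `no_cwt_sat`, `cwt_to_conv`, `cwt_to_se`, `cwt_to_wmsa`, `no_index_map`,
  `no_score_map`, `no_pc`, `no_kv_matching`, `no_fcwt` — each a pure
  model-config change trained under the identical seed and split.

## Reference sensitivity of the confidence map

The score map's purpose is to trust matched anatomy and suppress spurious
transfers. The package measures this at the matcher level: embedding the
bicubically upsampled LR query and the blurred reference key with one
shared SFE, a reference drawn from the same slice yields near-perfect mean
confidence (its blurred key is the degradation twin of the query — the
stated reason the key is degraded at all), strictly above an unrelated
phantom's. Through the full network the query and key pass through
independent encoders (CWT branch vs SFE), and nothing in the objective
optimizes matched-vs-unrelated discrimination, so no such gap is asserted
for the end-to-end model.

## Known limitations

- Pure-R training is practical at desk scale only; the full-scale profile
  is recorded as configuration, not re-run here.
- The perceptual fallback is a regulariser, not a perceptual metric; LPIPS
  and pretrained-VGG comparisons are out of scope offline.
- 2D slices only; no volumetric context, no multi-contrast conditioning,
  no k-space degradation models, no skull stripping.
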