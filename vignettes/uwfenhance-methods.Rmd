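---
title: "Methods: unpaired degradation enhancement and super-resolution for UWF retinal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unpaired degradation enhancement and super-resolution for UWF retinal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ultra-widefield (UWF) retinal photography images most of the retina in one
shot, but pays for its field of view with low macular resolution, blur,
uneven illumination, compression artifacts and noise.  Conventional fundus
photography delivers the opposite trade-off: a narrow field at high quality.
Supervised enhancement would need pixel-aligned UWF/fundus pairs, which are
practically impossible to acquire.  This package implements an *unpaired*
two-stage adversarial pipeline that learns from two independent image
collections — a UWF-like low-quality domain and a fundus-quality domain —
and maps a UWF image to a "fundus-quality" result at four times the input
resolution.

The pipeline has two generators applied in order:

* **GDE**, a degradation-enhancement network (an attention U-Net) that
  removes blur/illumination/compression artifacts at the input resolution;
* **GSR**, a ×4 super-resolution network (residual blocks plus two ×2
  pixel-shuffle stages).

Each generator is paired with an adversarial critic.  The low-resolution
critic compares enhanced UWF images against ×4 bicubic *downsamples* of real
fundus images (so both live at the same scale); the full-resolution critic
compares super-resolved outputs against real fundus images.  The two critics
share an architecture but never share parameters.

## Losses

With critic scores $D(\cdot)\in(0,1)$, the critic objective is the standard
cross-entropy form
$-\mathbb{E}[\log D(x_{real})] - \mathbb{E}[\log(1-D(G(z)))]$ and the
generator uses the non-saturating form $-\mathbb{E}[\log D(G(z))]$.  Scores
are clamped away from $\{0,1\}$ by $10^{-7}$ so every loss is finite.  The
enhancer stage adds two content terms:

* **identity loss** $\mathbb{E}\,|G_{DE}(z)-z|$ (L1), keeping the enhancer
  from redrawing content the adversary does not require it to change;
* **weight-anchor regulariser**: the mean squared deviation of the
  *non-frozen* enhancer parameters from their pretrained snapshot.  Frozen
  parameters cannot drift, so anchoring them would be vacuous.

The composite enhancer loss is
$L_E = L_{adv} + \lambda_I L_I + \lambda_R L_R$ with the canonical weights
$\lambda_I = 0.5$, $\lambda_R = 0.1$.  The super-resolution stage uses
$L_{SR} = L_{adv} + \lambda_C L_C$ with $\lambda_C = 0.5$, where $L_C$ is a
**one-way cycle loss**: real fundus images are bicubically downsampled by
×4, super-resolved, and compared (L1) to the originals.  There is no
reverse generator; the cycle runs one way only.  Macular fine-tuning
minimises $L_M = L_E + L_{SR}$ on patches restricted to the macular region.

Two notational points deserve mention.  The adversarial terms are sometimes
written in the literature with the algebraically unbounded form
"$1-\log D$"; we implement the standard bounded objective above.  Likewise
the cycle constraint is occasionally written with the critic inside the
cycle; a critic maps an image to a scalar, so the only executable reading
is the downsample-then-super-resolve round trip, which is what the
surrounding definitions describe and what we implement.

## Architectures

**GDE.** `depth` Conv boxes (3×3, stride 2: spatial halved, channels
doubled) form the encoder, mirrored by Deconv boxes (3×3 transposed
convolution: spatial doubled, channels halved) and a final 3×3 convolution
back to RGB.  After every Conv and Deconv box sits an Att box
(batch norm → activation → operation-wise attention → activation).  The
operation-wise attention module applies `n_attention_ops` parallel
channel-preserving candidates (1×1/3×3/5×5 convolutions at dilation 1 or 2,
plus 3×3 average pooling) and mixes them with per-image softmax weights
computed from a global-average-pooled two-layer gate.  Skip connections
between matching levels are *additive* rather than concatenating: this
keeps the "channels double down, halve up" arithmetic exact at every level
without widening the decoder.  Inputs not divisible by $2^{depth}$ are
zero-padded and cropped back.  Generator outputs are unbounded during
training and clipped to $[0,1]$ only at inference, keeping training
gradients unsaturated while guaranteeing valid images on disk.

**GSR.** A 3×3 feature extractor with PReLU, `n_residual_blocks` residual
blocks (Conv+BN, PReLU, Conv+BN, additive skip), a Conv+BN with a global
skip from the extractor, then $\log_2(scale)$ Conv+Shuffle stages (3×3
convolution to $4C$ channels, ×2 pixel shuffle, PReLU) and a channel
calibration to RGB.  The scale factor is fixed at 4 in the canonical
configuration.

**Critics.** A 3×3 feature extractor and a ladder of Conv+BN+LeakyReLU
blocks with strides alternating 2/1 and channels doubling every other
block, closed by global average pooling and a dense layer to one scalar,
mapped through a sigmoid.  Global average pooling in front of the dense
layer lets the same ladder score both the low-resolution and the
full-resolution pair without changing its parameter shapes; the two critics
are nonetheless always two independent parameter sets.

Activation conventions follow the respective base architectures: leaky
rectifiers in the enhancer and the critics, parametric rectifiers in the
upscaler.  The attention gate's final layer is initialised near zero so a
fresh module starts close to uniform mixing, and its 1×1 candidate is
identity-initialised.

## Training scheme

1. **Pretraining.**  The enhancer is pretrained with a supervised L1
   reconstruction loss on synthetic pairs: degraded phantom images as input
   and the ×4 bicubic downsample of the matching clean phantom as target
   (the enhancer preserves resolution, so supervision lives at the UWF
   scale).  The resulting parameters are snapshotted as the anchor.
2. **Stage DE.**  Adversarial adaptation of the enhancer with the encoder
   frozen (only decoder and attention groups update, which is also the
   anchored set).  Real examples for the critic are ×4 downsampled fundus
   patches; fakes are enhancer outputs on UWF patches of the same size.
3. **Stage SR.**  The enhancer is frozen entirely (all parameter groups,
   verified by checksum) and run in inference mode; the upscaler trains
   from scratch against the full-resolution critic plus the one-way cycle.
4. **Macular fine-tuning.**  Everything unfreezes; both stage losses are
   summed on patches whose centres lie in the macular region (taken from
   the phantom manifest when present, else a central disk of radius
   $0.25\,\min(H,W)$).  The fine-tuning critics are fresh networks trained
   at the fine-tuning rate; at desk scale this keeps the final calibration
   gentle — carrying the fully trained critics into this stage drives the
   low-rate generators off their reconstruction (an instability worth
   knowing about when scaling up).

The optimizer is AdamW with $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$
and decoupled weight decay $10^{-2}$ applied continuously — the optimizer's
native semantics.  The learning rate is halved every 200 000 iterations.
Canonical full-scale settings are batch 16 and 128-pixel fundus patches
(the UWF patch is a quarter of that, since the UWF domain lives at 1/4 the
linear resolution); augmentation is random 90° rotation and flips.
Checkpoints serialize parameters, optimizer moments, normalisation
statistics, the anchor and the RNG state, and resume bit-exactly.

### Desk-scale preset

The package's reference experiment (`run_experiment()`) runs the full
pipeline at desk scale: 64-pixel phantoms, tiny networks (base 8 channels,
depth 2, 4 residual blocks, 4 attention ops, 4 critic blocks), 500
iterations for pretraining/DE/SR and 200 for fine-tuning at batch 4 —
sized so the complete experiment, including evaluation, runs in roughly
ten minutes on one CPU core.

Learning rates in this preset follow a transfer-learning principle rather
than the full-scale value: components trained *from scratch* (pretraining,
the upscaler) use the canonical $10^{-3}$; adversarial *fine-tuning of the
pretrained enhancer* (stages DE and FT) uses $10^{-5}$, consistent with the
scheme's own anchor-and-freeze philosophy of preventing abrupt weight
change after pretraining.  The critics are fresh networks regardless of
the generator's state, so both adversarial stages first warm the critic up
for 50 iterations at $10^{-3}$ with the generator held fixed, then slow it
onto the generator's timescale ($2\times10^{-5}$ in the DE stage,
$10^{-4}$ in the SR stage).  Without the warm-up, the early adversarial
loss merely reflects the critic's random initialisation; without the
subsequent slow-down, the critic outpaces the generator long before the
500-iteration budget ends.  At a few hundred iterations the adversarial
game never reaches the asymptotic regime of a multi-million-iteration run;
these choices make the short run a stable refinement in which the
generator demonstrably gains on a calibrated adversary.

## The phantom generator

All experiments run on synthetic retinal phantoms with known ground truth.
A phantom contains: a radial-gradient orange/red background with smooth
low-frequency texture; a bright optic-disc ellipse on the nasal side;
dark curvilinear vessels grown from the disc by a seeded second-order
random walk with Gaussian cross-section stamping; a darker macular disc on
the temporal side; and optionally small bright drusen (disks of radius 1–3
px, +0.2 to +0.4 brightness) confined to a macular radius of size/6, whose
union is stored as the ground-truth mask.  UWF-like counterparts are
produced by a known degradation chain — by default Gaussian blur
($\sigma = 7$), uneven gamma illumination ($\gamma = 0.75$), JPEG
compression (rate 0.25) and ×4 bicubic downsampling, jointly — followed by
seeded additive Gaussian pixel noise (sd 0.01).

The two training domains are unpaired *by construction*: the UWF set is
generated from the same phantoms as the clean set but under a seeded
non-identity permutation, mirroring a shuffled clinical collection.  The
manifest retains the hidden pairing, per-phantom seeds and macula centres
so that tests can run paired oracles (PSNR against the hidden clean
counterpart) even though training never sees the pairing.

What the phantoms do *not* emulate: real retinal anatomy and pathology
variety, eyelash/eyelid occlusions and peripheral geometric distortion of
real UWF optics, scanner-specific artifacts, or the actual (uncharacterised)
degradation statistics of clinical UWF imagery.  Passing the package's
experiments therefore demonstrates that the training scheme and losses
behave as designed on a controlled domain pair — not clinical performance.

## Degradation operators

* **Gaussian blur**: the blur parameter is read as the kernel *support*
  ($\sigma\times\sigma$ pixels, rounded up to odd) with kernel standard
  deviation $\sigma/3$, so the kernel decays essentially to zero at its
  border; reflective edge handling.  The alternative reading (parameter =
  standard deviation) is noted but not used.
* **Uneven illumination**: per-pixel gamma correction
  $out(p) = img(p)^{g(p)}$ where $g$ ramps radially (cosine) from 1 at the
  image centre to $\gamma$ at the corners — a single smooth, parameter-free
  interpretation of "uneven", analytically testable at centre and corners.
* **JPEG**: encode/decode round trip at libjpeg quality
  $\mathrm{round}(100\cdot rate)$ — the only monotone bounded reading of a
  compression "rate" of 0.25.
* **Bicubic resampling**: separable cubic convolution ($a=-0.5$),
  half-pixel centres, no corner alignment, clamp-to-edge, and kernel
  widening by $1/scale$ when minifying (antialiasing).  `scale = 1` is the
  exact identity; outputs below 8 pixels are refused.

## Evaluation battery

* **Sharpness** (`sharpness_score`): a no-reference re-blur gradient-ratio
  blur estimate in $[0,1]$ — re-blur the luminance with a fixed 9-tap
  averaging filter and measure how much neighbouring-pixel variation
  survives; blurry images change little under re-blurring and score high.
  Lower = sharper.  A constant image returns 1 by documented convention.
  The published description of the sharpness metric used for this family
  of experiments is by citation only, so the estimator is exposed behind a
  named function that alternative implementations can replace.
* **IoU / mAP**: mask overlap $|A\cap B|/|A\cup B|$ (defined as 1 when both
  masks are empty), and its mean over images in percent.  The mAP here is
  *by definition* the image-averaged IoU, not detection-style AP over
  thresholds.
* **Group statistics**: classical one-way fixed-effects ANOVA
  (via `stats::oneway.test`, equal variances) with degenerate zero-variance
  cases flagged explicitly, and Bonferroni-corrected pairwise Welch t
  tests ($p_{adj} = \min(1, m\,p)$).
* **LPIPS / FID**: adapters only.  Both metrics are defined by fixed
  pretrained feature extractors; re-implementing them would add nothing.
  When no backend is registered the adapters return `NA` with a notice and
  reports still build.
* **Drusen detection**: a deliberately simple deterministic detector
  (luminance minus heavily blurred background, fixed threshold, restricted
  to the macular disk) used to compare lesion visibility before and after
  enhancement against the phantom ground-truth masks.

PSNR against the hidden paired clean phantom exists for test oracles only;
the headline evaluation is reference-free by design, because the method's
target domain has no aligned ground truth.

## Numerical choices and degenerate inputs

Critic probabilities are clamped at $10^{-7}$; batch-norm layers use
momentum 0.1, $\epsilon = 10^{-5}$, batch statistics during training and
running statistics at inference (a frozen enhancer always runs in
inference mode).  Convolution weights are He-initialised; the pixel-shuffle
channel-to-space bijection fills each 2×2 sub-grid column-offset fastest.
Images smaller than a critic's receptive minimum raise an explicit size
error; enhancer inputs of awkward sizes are padded and cropped instead.
Cycle-loss inputs not divisible by 4 are cropped to the largest multiple.
All randomness flows from explicit seeds through a documented fan-out
(`derive_seed`), making phantoms, datasets, initialisation and training
runs bit-reproducible; checkpoints restore the RNG state exactly.

## Known limitations

* Pure-R training is CPU-bound; the desk-scale preset is minutes, but the
  full-scale configuration (64 base channels, millions of iterations) is
  far outside this implementation's intended envelope.
* The adversarial game at a few hundred iterations is a transient, not an
  equilibrium; conclusions about the full-scale method's asymptotic
  behaviour cannot be drawn from the miniature experiment.
* The phantom domain is statistically simple; absolute metric values on
  phantoms do not transfer to clinical images.
* The order ablation (super-resolve first, enhance second) is exposed as an
  inference-composition entry point; re-training the whole pipeline in the
  reversed order is out of scope.
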