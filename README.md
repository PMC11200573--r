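# uwfenhance

Unpaired degradation enhancement and ×4 super-resolution for
ultra-widefield (UWF) retinal images, in pure R.

UWF photography captures most of the retina in a single shot but suffers
from low macular resolution, blur, uneven illumination, compression
artifacts and noise; conventional fundus photography is sharp but narrow.
Aligned UWF/fundus image pairs for supervised learning are practically
unobtainable. `uwfenhance` implements an unpaired dual-GAN pipeline that
learns from two independent image collections and maps a UWF image to a
fundus-quality result at 4× resolution:

* **GDE** — an attention U-Net enhancer (operation-wise attention after
  every Conv/Deconv box) that removes degradations at the input scale;
* **GSR** — a residual pixel-shuffle upscaler (×4);
* twin adversarial critics (low-resolution and full-resolution, identical
  architecture, independent parameters).

Training is staged: supervised pretraining of GDE on synthetic pairs, then
adversarial adaptation with the encoder frozen (loss
`L_E = L_adv + 0.5·L_identity + 0.1·L_anchor`, where the anchor term ties
the adapted weights to the pretrained snapshot), then GSR training with
GDE fully frozen (`L_SR = L_adv + 0.5·L_cycle`, with a one-way cycle:
fundus → ×4 bicubic downsample → GSR → compare to the original), and
finally joint fine-tuning on macular patches (`L_M = L_E + L_SR`).
Optimisation is AdamW (β = 0.9/0.999, eps 1e-8, weight decay 1e-2) with the
learning rate halved every 200k iterations.

Because clinical data cannot ship with a package, `uwfenhance` includes a
seeded retinal phantom generator (vessel trees, optic disc, macula, bright
drusen with ground-truth masks) and four parametrized degradation
operators (Gaussian blur σ=7, uneven gamma illumination γ=0.75, JPEG
rate=0.25, bicubic scale=0.25) that synthesize the UWF-like domain with
known ground truth. The evaluation battery implements the no-reference
re-blur sharpness score (lower = sharper), lesion-mask IoU and mean
average precision (mean IoU in percent), one-way ANOVA and
Bonferroni-corrected pairwise tests, plus optional LPIPS/FID adapters.

All neural-network machinery (reverse-mode autodiff over 4-d arrays,
convolution/transposed convolution/batch norm/pixel shuffle/attention,
AdamW) is implemented in R and verified against finite differences; the
whole reference experiment runs on one CPU core in about ten minutes.

## Worked example

```r
library(uwfenhance)

# a clean phantom and its UWF-like degradation
params <- phantom_params(size = 64, n_drusen = 5)
ph  <- generate_phantom(params, seed = 7)
uwf <- synthesize_uwf(ph, default_uwf_chain(), seed = 7)
dim(uwf)                     # 16 16 3  (x4 downsampled by the chain)

# the full miniature experiment: dataset -> pretrain -> DE -> SR -> FT
res <- run_experiment(seed = 1)
str(res$metrics)
#> $ psnr_raw           : num 24
#> $ psnr_enhanced      : num 24.3
#> $ sharpness_enhanced : num 0.121
#> $ sharpness_bicubic  : num 0.642
#> $ drusen_iou_enhanced: num 0.0178
#> $ drusen_iou_degraded: num 0
#> $ n                  : int 16
```

Reading: on 16 held-out phantoms the enhancer output is closer to the
hidden clean counterpart than the raw degraded input (PSNR 24.3 vs
24.0 dB); the full ×4 enhancement scores sharper (lower) than plain
bicubic upsampling on the re-blur metric (0.12 vs 0.64); and a simple
bright-blob drusen detector overlaps the ground-truth masks better on
enhanced images than on bicubic-upsampled inputs (IoU 0.018 vs 0).

Enhance a single image with trained networks:

```r
out <- enhance(uwf, res$enhancer, res$upscaler)   # 64 x 64 x 3
```

## Command line

A thin wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/uwfenhance synth --n 8 --seed 1 --out data/
Rscript inst/cli/uwfenhance degrade --kind gaussian_blur --sigma 7 in.png out.png
Rscript inst/cli/uwfenhance train --stage all --config run.yaml
Rscript inst/cli/uwfenhance enhance in.png out.png --ckpt run/checkpoints
Rscript inst/cli/uwfenhance evaluate --pred-dir out/ --ref-dir ref/ --out report.json
```

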