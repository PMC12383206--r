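---
title: "Mask-conditioned diffusion augmentation for cardiac MR segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-conditioned diffusion augmentation for cardiac MR segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Supervised cardiac MR segmentation needs pixel-accurate annotations of the
left-ventricular cavity (LV), left-ventricular myocardium (MYO) and
right-ventricular cavity (RV), which are expensive to produce. `cardiacaug`
implements a two-stage generative augmentation strategy that manufactures new
*paired* training data from noise:

1. **Stage 1 — pseudo-labels.** An unconditional denoising diffusion
   probabilistic model (DDPM) is trained on the one-hot encoded multi-class
   masks themselves. The forward process corrupts a mask tensor $y_0$ with
   Gaussian noise through a variance schedule $\{\beta_t\}_{t=1}^T$,
   $\alpha_t = 1-\beta_t$, $\bar\alpha_t = \prod_{i\le t}\alpha_i$, using the
   closed form
   $y_t = \sqrt{\bar\alpha_t}\,y_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$. A
   U-Net $\epsilon_\theta(y_t, t)$ is trained with the simplified
   epsilon-matching loss
   $\mathbb{E}\,\lVert \epsilon - \epsilon_\theta(y_t,t)\rVert_2^2$ and new
   masks are drawn by reversing the chain — ancestral (DDPM) sampling or
   accelerated DDIM over a 50-step subsequence of the 1000 training steps.
2. **Label screening.** Generated masks are filtered by four morphological
   plausibility rules (below) before they are allowed to condition image
   synthesis.
3. **Stage 2 — pseudo-images.** A compression autoencoder maps images to a
   latent space; a second diffusion model is trained on the latents with the
   same loss, conditioned on the (resized, one-hot) mask through SPADE
   modulation in its decoder. Classifier-free guidance
   $\hat\epsilon = \hat\epsilon_u + w(\hat\epsilon_c - \hat\epsilon_u)$
   steers sampling; each accepted pseudo-label yields exactly one
   pseudo-image.

The augmented pairs are appended to the real training set of a U-Net
segmenter, and the package's harness compares that regime against classical
augmentation (affine, elastic, intensity, CutMix) on a shared held-out test
split, reporting per-class and mean Dice (DSC) and IoU.

## What the phantom generator emulates

All tests and the acceptance pipeline run on synthetic short-axis phantoms:
a bright LV disk enclosed by a darker myocardial ring with a bright RV
crescent attached laterally, per-class mean intensities in $[-1,1]$, a
smooth low-order polynomial multiplicative bias field standing in for coil
inhomogeneity, and additive Gaussian noise. Geometry (radii, thickness, RV
angle, center jitter) is drawn per case from a seeded RNG, so a spec plus a
seed reproduces a phantom bit-for-bit. Cases are split 7:1:2 by whole case
after a seeded shuffle, mirroring patient-level splitting; 50 cases split
35/5/10 and 94 split 66/9/19.

The phantoms deliberately do **not** model real anatomy: no pathology, no
papillary muscles, no through-plane variation, no multi-vendor intensity
statistics. Passing tests on phantoms therefore demonstrates that the
machinery is correct and that the pipeline's ordering claim (diffusion
augmentation does not hurt, and tends to help, a data-limited segmenter)
holds under controlled conditions — not that the absolute published
accuracies on clinical data are reproduced. Reproducing those numbers would
require the M&Ms cohort and GPU-scale training, which is out of scope here;
the NIfTI ingestion path (`read_cardiac_volume`) exists for users who have
such data.

## The screening rules

Four abnormality conditions reject a generated mask: (1) a cardiac class
fragmented into several connected components; (2) topology violating
short-axis anatomy; (3) vanishing foreground occupation; (4) many stray
speckle components in the background. The rules needed operationalizing:

* **Rule 2 concretization.** "Clinical logic" is read, for a short-axis
  slice, as: every LV boundary pixel's 8-neighborhood outside the LV
  contains only myocardium (the cavity never touches background or RV
  directly), and any RV component touches the myocardium. A mask missing LV
  or MYO fails outright; a mask without RV is allowed (apex-like slice).
* **Speckle jurisdiction.** A handful of isolated noise pixels would
  otherwise trip rules 1 and 2 before rule 4 could ever fire. Components of
  at most `speckle_max_px` pixels (default 4) are therefore treated as
  background speckle: invisible to the structural rules 1–2, counted by
  rule 4 as stray components (total per-class components minus one per
  present class). Rules 3–4 always see the raw mask.
* **Thresholds.** `min_foreground_fraction = 0.01` (strictly below fails),
  `max_background_components = 5`, `enclosure_tolerance = 0`, connectivity
  8 throughout (tolerant of diagonal joins typical of generated masks). All
  are exposed in `filter_config()`; loosening a threshold can only grow the
  accepted set (a tested monotonicity property).

## Networks and numerical choices

No deep-learning framework is assumed: the package carries its own
reverse-mode autodiff tape over dense arrays with Rcpp/Armadillo im2col
convolution kernels, validated against central finite differences in the
test suite. Architectural conventions follow standard DDPM/LDM practice:

* U-Net with residual blocks (two group-normalizations and 3×3
  convolutions, additive per-channel timestep embedding, learned 1×1
  shortcut on width changes), strided-convolution downsampling,
  nearest-neighbor + convolution upsampling, channel-concatenated skips,
  and single-head self-attention at the configured levels. The full-scale
  mask model is six levels at widths 64–1024 (the five published widths
  completed monotonically to six levels) with attention in the last three;
  toy runs use three levels at 8/16/32 with attention at the coarsest
  level, preserving the shape of the design.
* Sinusoidal timestep embeddings (dimension `4 * channels[1]`), SiLU
  activations throughout.
* The conditional variant swaps decoder-resblock normalization for SPADE:
  parameter-free group normalization scaled and shifted by spatial
  $\gamma(m), \beta(m)$ maps computed from the nearest-neighbor-resized
  one-hot mask by a small two-convolution head. The $\gamma/\beta$ output
  convolutions are zero-initialized, so at initialization the conditional
  network computes exactly the unconditional function (a tested identity);
  shared weights are drawn from the same seeded stream in both variants.
  The condition enters only through the decoder; the encoder is plain
  resblocks and attention.
* Near-zero (gain 0.05) initialization for residual-output, attention-output
  and head convolutions: close enough to identity to stabilize early
  training while keeping gradient flow to every parameter testable.
* Variance schedule: linear $\beta$ from $10^{-4}$ to $0.02$ over
  $T = 1000$ steps (the standard DDPM recipe; the source architecture text
  leaves it unspecified). The reverse-step noise scale is fixed, not
  learned — $\sigma_t^2 = \beta_t$ by default, with the forward-posterior
  variance available as an option (the two standard fixed choices; the
  epsilon-matching loss trains no variance head). $\sigma_1 = 0$ so the
  final reverse step is deterministic.
* DDIM uses an evenly spaced decreasing timestep subsequence including
  $T$ and 1, with $\eta = 0$ by default. During mask sampling the
  intermediate clean estimate $\hat y_0$ is clamped to $[-1,1]$ (the
  encoding's range), which markedly stabilizes sampling from lightly
  trained models; latent-space sampling is not clamped because latents are
  unbounded. Mask generation itself uses the stochastic sampler
  ($\eta = 1$): the fresh noise injected at every step repeatedly
  re-anchors the trajectory on the learned manifold, which at short
  training budgets turns fragmented deterministic samples into clean
  ones. With a fixed seed the stochastic sampler is still exactly
  reproducible.
* Optimization: Adam with linear warmup (a tenth of the run, capped at 100
  steps) to the configured peak rate, then cosine decay to 2% of the peak.
  Full-scale defaults follow the published setup (peak $10^{-4}$, batch 16;
  segmenter weight decay $10^{-5}$); toy runs use larger peaks
  ($10^{-3}$–$2\times10^{-3}$) suited to their small widths. The diffusion
  trainers optionally maintain an exponential moving average of the
  weights (`ema_decay`, off by default); the toy runs enable it
  (0.995–0.997), the usual stabilizer for diffusion sample quality under
  short training.
* Mask encoding: one-hot over the four classes mapped to $\pm 1$ rather
  than scalar class indices, avoiding a false ordinal metric under Gaussian
  noise. Decoding is per-pixel argmax with ties broken toward the lowest
  class index (background-favoring, hence conservative for screening).
  Nearest-neighbor mask resizing preserves one-hotness exactly; downscaling
  takes the top-left pixel of each block.
* The autoencoder (five levels 64–1024 at full scale, group normalization,
  factor $f = 8$, i.e. 128×128 → 16×16 latents with 4 channels; toy:
  three levels 8/16/32 with $f = 4$) trains on L1 reconstruction plus a
  $10^{-6}$-weighted KL pull of its diagonal-Gaussian latent toward the
  standard normal, with a tanh output in $[-1,1]$. No adversarial or
  perceptual terms — a deliberate simplification of "perceptually
  equivalent" that keeps the artifact desk-scale; a single learning rate is
  used (the published "varying learning rates across data subsets" is not
  specified precisely enough to reproduce). The autoencoder is frozen while
  the latent diffusion model trains (the two stages are sequential by
  design); the latent mean is used as the code.
* Classifier-free conditioning: condition dropout probability 0.1
  (replacement by the all-background null mask), default guidance weight
  1.5 — standard values, both exposed in configuration.
* Segmentation loss: cross-entropy plus soft Dice (equal weight), the
  standard pairing for class-imbalanced cardiac segmentation; no loss is
  named in the source description. Per-class metrics define DSC = IoU = 1
  when a class is absent from both masks and 0 when absent from exactly
  one, so hallucinated or missed structures are penalized without 0/0.

## The augmentation comparison

`run_experiment()` trains one segmenter per regime on identical real data
plus regime-specific generated pairs, under an equal gradient-step budget
(`max_steps`), then evaluates every model on the same held-out test pairs.
The diffusion regime samples masks in chunks, screens them, keeps up to
`n_aug`, and synthesizes one image per accepted mask. How many synthetic
pairs to add is not pinned down by the source description; the harness
default is one per real pair, and the scaled-down acceptance run adds 40
to 140 real pairs, matching the label filter's realistic yield at toy
training budgets.

## Problem sizes used by the tests and the acceptance run

The package's own study conditions (chosen once for a single CPU, stated
here as the experiment design): 200 phantoms at 32×32 split 140/20/40; the
toy mask DDPM trains for 2000 steps at batch 8 (peak rate
$1.5\times10^{-3}$); 64 masks are sampled with 50-step DDIM for screening;
the memorization check trains 1500 steps (batch 4) on a single repeated
mask; the
autoencoder trains 800 steps and the conditional LDM 1200 steps; segmenters
get 150 gradient steps per regime. At these budgets the mask model's
samples are imperfect — the screening filter typically accepts a minority
of them, which is precisely the regime the filter exists for.

## Known limitations

* Phantom realism, as above; absolute clinical accuracies are not claimed.
* The generative stack at toy scale is undertrained by design; sample
  quality statements are qualitative (pass-rate positive, ordering of
  regimes) and stochastic under fixed seeds.
* Single-head attention only; no EMA weight averaging; no learned
  variances, alternative schedules, or classifier guidance — all outside
  the implemented design.
* Everything runs in double precision on one CPU; wall-clock, not
  statistical, considerations set the toy sizes above.
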