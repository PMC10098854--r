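---
title: "Conditional adversarial lesion segmentation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional adversarial lesion segmentation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation model

`dermcgan` frames lesion segmentation as conditional image-to-image
translation. A generator $G$ maps a dermoscopic image $x$ (and implicit noise
$z$) to a candidate segmentation image $G(x, z)$; a discriminator $D$ judges
whether a (source, target) pair is a real annotation or a generated one. The
conditional adversarial objective is

$$\mathcal{L}_{cGAN}(G, D) = \mathbb{E}_{x,y}[\log D(x, y)] +
  \mathbb{E}_{x,z}[\log(1 - D(x, G(x, z)))],$$

and the generator is additionally pulled toward the ground truth $y$ by an L1
term, giving the combined objective

$$G^{*} = \arg\min_G \max_D \mathcal{L}_{cGAN}(G, D) +
  \lambda\, \mathcal{L}_{L1}(G), \qquad
  \mathcal{L}_{L1}(G) = \mathbb{E}_{x,y,z}\lVert y - G(x,z)\rVert_1 .$$

The noise $z$ is realized purely as dropout in the decoder, active at
training time and (optionally) at prediction time; there is no explicit noise
vector.

**Generator.** A U-Net: seven encoder blocks (4×4 convolutions, stride 2,
widths 64, 128, 256, 512, 512, 512, 512, each followed by normalization and
LeakyReLU with slope 0.2), a bottleneck convolution with ReLU reaching 1×1
spatial size, and seven mirrored decoder blocks (4×4 transposed convolutions,
stride 2, normalization, dropout 0.5 in the innermost three blocks, ReLU),
each concatenated with its mirror encoder activation. A final transposed
convolution with tanh emits a 3-channel image in $[-1, 1]$. Weights
initialize from a zero-mean normal with $\sigma = 0.02$.

**Discriminator.** A PatchGAN: source and target are concatenated on
channels (6 input channels) and passed through five 4×4 convolutions of
widths 64, 128, 256, 512, 512, each followed by normalization and
LeakyReLU(0.2), then a 1×1 convolution with sigmoid. Each cell of the
resulting 32×32 patch map (for 256×256 inputs) judges one patch of the
input; the receptive-field recurrence $RF_{in} = (RF_{out}-1)s + k$ folded
through the chain gives exactly 70 pixels per side.

### Design choices that were genuinely open

* **Discriminator stride schedule.** Five stride-2 4×4 layers plus a head
  cannot produce a 70-pixel patch; strides 2, 2, 2, 1, 1 with a 1×1 head give
  exactly 70 by the recurrence while keeping the five published widths. This
  schedule is the package default, and `receptive_field()` exposes the
  arithmetic.
* **Normalization.** Batch normalization is applied after every
  discriminator convolution and in every generator block except the
  bottleneck and output layers. With batch size 1 (the training regime),
  batch statistics coincide with per-sample spatial statistics, so the
  implementation normalizes over the spatial dimensions of the single sample.
  This keeps prediction fully deterministic as a function of the input, with
  no running averages to maintain. One consequence is that normalization
  couples all pixels of a channel through its statistics, so strict
  single-pixel receptive-field locality holds only for an unnormalized
  network; the `normalized` spec toggle exists so diagnostics can verify
  the pure convolution geometry.
* **Generator output.** Three channels with tanh, matching RGB-encoded
  ground-truth files, with the mask replicated across channels as the
  regression target; predictions are collapsed by luminance and thresholded
  at 0.5 (ties to foreground) for evaluation.
* **$\lambda = 100$.** The canonical weighting for adversarial-plus-L1
  translation; it makes the L1 term dominant early, which segmentation
  benefits from. Exposed in `train_config()`.
* **Batch size 1, Adam for both models** with learning rate 0.0002 and
  $\beta_1 = 0.5$; no label smoothing and no learning-rate decay, keeping
  the loop minimal. The innermost skip connection is omitted (the bottleneck
  feeds the first decoder block directly), the standard wiring for
  U-Net-in-GAN generators.
* **Dropout placement.** Decoder dropout of 0.5 after normalization, in the
  three innermost blocks: high-resolution outer features stay stable while
  the coarse features carry the stochasticity. Prediction defaults to
  deterministic mode (dropout off); stochastic mode requires a seed so runs
  remain reproducible.

## Preprocessing

Dermoscopic images carry hairs, air bubbles and sensor noise. The chain is
Gaussian smoothing, then grayscale morphological closing, then unsharp
sharpening:

* `gaussian_smooth(image, sigma = 1)`: separable normalized Gaussian,
  radius $3\sigma$, reflect padding. $\sigma = 1$ px denoises mildly without
  blurring lesion borders at 256×256.
* `morphological_close(image, selem_radius = 5)`: per-channel max-filter then
  min-filter over a disk. Closing is extensive, increasing and idempotent;
  dark structures narrower than the disk (hairs, 1–3 px) are lifted to the
  surrounding intensity while wide dark regions (lesions) survive. Radius 5
  at 256×256 clears typical hair widths with margin. Border handling ignores
  out-of-bounds positions, equivalent to padding with the identity elements
  of max/min.
* `sharpen(image, amount = 1, sigma = 1)`: unsharp masking,
  $\mathrm{clip}(x + a(x - \mathrm{blur}(x)))$ — the parameterized
  generalization of the common 3×3 sharpening kernel.

The element shape, $\sigma$, and the sharpening kernel are not pinned down
by the published description; all are config-exposed with the defaults
above. The mask is never touched by preprocessing.

## Augmentation

`augment_pair()` emits, per input, 3 right-angle rotations plus 4 sides × 3
graded crops = 15 pairs, with left-right flip and a (25, 25) shift available
but off by default: the published grid lists 17 operations but states 15
samples per image, and 3 + 12 is the only subset consistent with that count.
Crop settings are printed as "45°, 60°, 90°" — degrees are meaningless for
crops, so they are read as retain-percentages 45 %, 60 %, 90 %. Crops are
resized back to the working resolution (bilinear image, nearest-neighbour
mask) so every sample shares one tensor shape. All transforms apply
identically to image and mask; alignment is asserted in tests by comparing
image-darkness and mask centroids on synthetic scenes.

## Synthetic dermoscopy scenes

The simulator exists so every pipeline stage is testable without downloads.
A scene is a skin-toned background (5-entry beige/brown palette) with one
darker lesion whose boundary is an ellipse modulated by a random harmonic
series of orders 3–8 (amplitudes normalized so their sum equals the
irregularity parameter), plus optional dark cubic-Bézier hair strokes
(width 1–3 px), bright bubbles (radius 2–6 px) with darker rims, and
additive Gaussian noise. The mask is the rendering predicate itself —
artifacts draw on the image only — so ground truth is exact by
construction. Each component (lesion shape, hairs, bubbles, noise) draws
from its own seed substream, so re-rendering without hairs changes nothing
else; the artifact-removal tests rely on this.

Difficulty regimes: *easy* scenes have contrast 0.5–0.9, irregularity
0.02–0.15, 0–3 hairs, 0–2 bubbles, noise sd 0.01–0.03; *hard* scenes have
contrast 0.1–0.3, irregularity 0.15–0.35, 5–12 hairs, 2–6 bubbles, noise sd
0.03–0.06. These ranges make global Otsu thresholding succeed on clean easy
scenes (Dice ≥ 0.85) and fail on hard ones — the regime contrast that
motivates a learned segmenter — while a tiny cGAN trained on 200 easy
64×64 scenes for 2000 steps reaches mean Dice well above 0.8 on held-out
scenes.

What the simulator does **not** emulate: real lesion texture (pigment
networks, globules), specular gel reflections, ruler markings, vignetting,
and the intra-class variability of real datasets. Passing tests demonstrate
that the implementation optimizes its objective and that the pipeline's
geometry and bookkeeping are correct — not that the model reaches any
particular accuracy on clinical data.

## Evaluation metrics

From pixel confusion counts: accuracy $(TP+TN)/N$, Dice
$2TP/(2TP+FP+FN)$, Jaccard $TP/(TP+FP+FN)$, sensitivity $TP/(TP+FN)$ —
and two specificities. The published formula prints specificity as
$TP/(TP+FP)$, which is mathematically a precision; `specificity_paper`
computes exactly that (used wherever the published table format is
mirrored), and `specificity_standard` computes $TN/(TN+FP)$ alongside it.
Any 0/0 denominator yields 1 when prediction and truth agree on the relevant
class and 0 otherwise, and the metric is flagged in the output. Dice and
Jaccard satisfy $D = 2J/(1+J)$ identically; the tests assert this to 1e-12.
Metrics are computed at the 256×256 working resolution (or the model's
native resolution), not at source resolution.

## Numerical engine

No R deep-learning runtime is involved: convolution, transposed
convolution, normalization, activations, dropout and Adam are implemented
in the package (C++ im2col/GEMM via RcppArmadillo for the convolutions).
Transposed convolution is realized as the data-gradient of the matching
strided convolution, which makes the adjointness testable. "Same" padding
follows the ceil-mode convention with the smaller half of the padding
before. Every layer gradient is validated against central finite
differences (tolerance 1e-6 at step 1e-6) on micro-scale models in the test
suite. Training is bit-reproducible for a fixed seed on one device: one RNG
stream drives initialization, shuffling and dropout.

### Problem sizes used in verification

Tests run at deliberately small scales chosen to exercise every code path
while keeping the suite quick: micro models at 8–16 px for gradient and
bookkeeping checks, the tiny 64-px generator/discriminator for optimization
behaviour (single-pair regression under dominant L1; 200-scene end-to-end
training with 16 held-out scenes), and 96–128 px scenes for morphology and
thresholding properties. The default 256-px architecture is exercised for
construction, shape and receptive-field arithmetic.

## Known limitations

* CPU-only and batch size 1; no multi-GPU, no mixed precision. Training the
  full 256×256 architecture to convergence is out of desk scope.
* The simulator's simplicity means reported synthetic Dice values say
  nothing quantitative about DermIS/DermQuest/ISIC performance.
* Dropout-as-noise at prediction time is faithful to the published
  procedure but rarely what an evaluator wants; evaluation therefore
  defaults to deterministic mode and records that choice.
* Checkpoints serialize weights with R's native format plus a JSON
  architecture sidecar; they are not portable to other frameworks.
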