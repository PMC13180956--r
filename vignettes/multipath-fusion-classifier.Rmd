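---
title: "A multipath residual channel-attention classifier with robust Huber losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multipath residual channel-attention classifier with robust Huber losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusnetcnn)
```

## The problem

Leaf-disease classification from RGB photographs is a multiclass image
problem with two practical constraints: disease symptoms of different
classes overlap visually, and field deployments cannot afford large
models. `fusnetcnn` implements a deliberately lightweight convolutional
classifier built around three ideas — a *wide* rather than deep residual
trunk (multipath residual groups with channel attention), *sub-pixel
fusion* of early high-frequency features with the trunk output, and a
*robust Huber-type training loss* whose gradient is bounded, so gross
outliers (mislabeled images, extreme illumination) cannot dominate an
update.

Everything here — forward passes, backward passes, the optimizer — is
implemented in R with small compiled kernels for the convolution
primitives (`im2col`/`col2im`, pooling, the median filter), and every
layer's analytic gradient is verified against finite differences in the
test suite.

## Preprocessing

Images enter the network after two steps:

1. **Median filter** (default 3×3, symmetric-reflection borders),
   applied per channel on the integer image. The median is the standard
   denoiser for impulse noise and harsh shadow speckle: it removes
   isolated extreme pixels without blurring lesion edges.
2. **Min–max normalization** to the unit interval,
   $X' = (X - X_{\min})/(X_{\max} - X_{\min})$, with the statistics
   taken per image over all channels jointly. Per-image statistics keep
   inference stateless (no dataset pass is required); a constant image
   maps to all zeros rather than raising an error, so pipelines stay
   total.

## Architecture

The default configuration (`net_config()`) takes 128×128×3 input and
produces 38 class probabilities (the Plant Village class count).

**Stem.** Three stages of convolution → batch normalization → ReLU →
2×2 stride-2 max pooling, with 16, 32, and 64 kernels. The three BN
layers therefore carry exactly 32, 64, and 128 trainable parameters
(γ and β per channel); ε defaults to $10^{-5}$. The first-stage
activation *before* pooling is kept aside as the low-level map
$F_L$ (128×128×16): the earliest layer holds most of the
high-frequency content worth preserving.

**Residual channel-attention (RCA) block.** Two 3×3 convolutions with a
ReLU between them, then channel attention: global average pooling to a
per-channel descriptor, a bottleneck (reduction 4) with ReLU, expansion
with a sigmoid gate, channelwise multiplication, and a short skip
adding the block input. With all-zero weights the block is exactly the
identity — a property the tests assert bitwise.

**Residual group (RG).** $N = 2$ chained RCA blocks, a 3×3 tail
convolution, and a long skip: $O = I + W_{tail}(\mathrm{RCA}_N(\cdots))$.

**Multipath trunk.** Two parallel paths over the stem output: two
stacked RGs, and one RG; their outputs are summed. This widens the
network (three RGs total at 64 channels) instead of deepening it, which
is what keeps the parameter count low. Under zero weights the sum
degenerates to exactly twice the input.

**Pixel-shuffle fusion.** The trunk output (16×16×64) passes through a
convolution to $32 \cdot a^2$ channels; $F_L$ passes through a stride-8
convolution to the same 16×16 grid and channel count. Both are
rearranged by the sub-pixel (pixel shuffle) mapping
$\mathrm{out}(i,j,c) = \mathrm{in}(\lfloor i/a\rfloor, \lfloor j/a\rfloor,\;
C a\,(i \bmod a) + C\,(j \bmod a) + c)$
with scale factor $a = 2$ and summed, yielding a 32×32×32 fused map.
The mapping is a bijection (value multisets are conserved), and the
stride-8 projection is the design choice that reconciles the two
branches' spatial grids, which the architecture sketch leaves open.

**Heads.** Classification: global average pooling, one fully connected
layer, softmax. Optionally a reconstruction head (a convolution to 3
channels) can be enabled; its mean-absolute (L1) distance to the
block-averaged input enters the objective with weight λ (default 0, so
the branch is inert unless asked for — the surrounding evaluation is a
classification task).

**Complexity.** The package counts complexity analytically from a layer
manifest: parameters as the exact number of trainable scalars, and
forward cost in the MAC convention (one operation per
multiply–accumulate in convolutions and fully connected layers; bias
additions, pooling, activations and BN are not counted).

```{r budget}
cfg <- net_config()
count_parameters(cfg) / 1e6   # millions of parameters
count_flops(cfg) / 1e9        # GFLOPs per forward pass
```

The defaults (input 128×128, kernel 3×3, $N = 2$, reduction 4, width
64) are the smallest standard settings of this block family; they land
the model under 0.7 M parameters and 0.21 GFLOPs.

## The loss family

For probabilities $p$ and one-hot labels $y$, the Huber-type losses act
on the residuals $e = p - y$ elementwise, averaged over classes and then
over the batch:

* **Huber (as printed in its source):** $0.5e^2$ for $|e| \le \delta$,
  else $\delta|e| - 0.5\,\delta$. The linear branch subtracts
  $0.5\delta$ — *not* $0.5\delta^2$ — so the function has a jump of
  $0.5\,\delta(\delta - 1)$ at the transition, vanishing only at
  $\delta = 1$. The package implements this form deliberately and keeps
  it distinct.
* **Improved Huber:** $0.5e^2$ for $|e| \le \delta$, else
  $\delta|e| - 0.5\,\delta^2$ — continuous with continuous first
  derivative at the transition for every $\delta$, gradient bounded by
  $\delta$, and never above $0.5e^2$. At $\delta = 1$ the two families
  coincide *exactly*, which the tests exploit: identically seeded
  training runs under the two losses are bitwise identical.

δ defaults to 1.0 throughout. The comparison suite adds cross-entropy
(probabilities clamped to $[10^{-12}, 1]$ before the log), focal loss
(focusing exponent γ = 2), and an exponential loss defined as
$\exp(-m)$ on the ±1-encoded one-vs-rest margin $m = t\,(2p - 1)$,
averaged over classes. The exponential loss is strictly positive even at
a perfect prediction (its minimum is $e^{-1}$); the others vanish there.

## Optimization

Adam (learning rate $10^{-3}$, β = 0.9/0.999), batch size 32,
stratified 80/10/10 split, best-validation-accuracy checkpointing —
all seeded, so a configuration and seed reproduce a run bit for bit in
a fixed environment. Validation accuracy decides the checkpoint; ties —
common once a small validation split saturates at 100% — resolve to the
epoch with the lower validation loss, which favours the more-converged
of equally accurate models.

One numerical choice deserves its own paragraph: the learning rate
warms up linearly over the first 30 updates (configurable). Adam's
first step moves every weight by roughly the full learning rate
regardless of gradient magnitude; in a fresh network that coherent jolt
can push the logits deep into softmax saturation. Cross-entropy
recovers — its gradient does not vanish under saturation — but the
Huber-type losses act on probabilities, whose gradient passes through
the softmax Jacobian and collapses to exactly zero on saturated rows.
Without warmup such runs visibly freeze at chance accuracy; with it
they train smoothly. This is an internal optimizer detail, not a change
to the training conditions.

Batch normalization uses batch statistics in training mode (batches of
at least two), population (biased) variance for both normalization and
the running update (momentum 0.1), and running statistics at inference.

## The synthetic data generator

`generate_leaf_set()` emulates the structure of class-per-directory
leaf datasets at desk scale: an elliptical green leaf (jittered center,
axes, rotation) on a soil-toned background, class-dependent lesion
spots (count range, radius range and color per class; class 1 is
lesion-free), an optional terraced linear illumination ramp
(0.75×–1.25×), and salt-and-pepper impulse noise at a configured rate
(default 2% of pixels). Textures are low-frequency by construction —
coarse random fields bilinearly upsampled and quantized into flat
terraces — so the *only* high-frequency content is the impulse noise,
and the median filter's denoising role is cleanly exercised: on
impulse-free images the filter touches only the corner pixels of
rasterized curved edges (a few percent), while on noisy images it
strictly reduces extreme-valued pixels.

Label corruption is exact-count, not binomial: exactly
`round(rate × total)` images are reassigned a uniformly chosen wrong
class and flagged in the manifest, so tests need no tolerance. The
default is 4 classes at 128×128; the 38-class layout is exercised
structurally with 2 images per class.

What the generator does *not* emulate: photographic texture, specular
highlights, occlusion, background clutter, or intra-class symptom
progression. Passing tests on this data demonstrate that the
architecture, losses, optimizer and bookkeeping are implemented
correctly and can learn a color/shape-separable task — they say nothing
about accuracy on real Plant Village or RoCoLe photographs, whose
headline numbers require full-scale training on the real images.

## Desk-scale experiment sizes

The test suite trains real models, at sizes chosen so the whole suite
stays comfortably inside a desktop run: the learning check uses 3
classes × 100 images at 64×64 for 15 epochs (median test accuracy over
3 training seeds must reach 0.95); the δ = 1 coincidence check uses 45
images at 24×24 for 3 epochs; the ablation table runs its six variants
(stem-only CNN; +RG; +multipath; +pixel-shuffle fusion; stem CNN with
improved Huber; full model with improved Huber) at 16×16 with 1 epoch
purely to validate shape and bookkeeping. The robustness property is
checked on a linear toy — slope fitting by gradient descent under 20%
gross outliers, where the improved-Huber estimate must beat least
squares in at least 18 of 20 replicates.

## Degenerate inputs and edge policies

* Constant image → min–max normalization returns all zeros.
* Even median window, channel counts other than 1/3, intensities
  outside [0, 255] → classed errors (`fusnet_invalid_parameter`,
  `fusnet_invalid_input`).
* Input sizes must be divisible by 8 (three stride-2 pools); a 1×1
  input is a configuration error.
* Training-mode batch normalization rejects batches of one; the train
  loop drops a trailing singleton batch.
* Zero-denominator metrics: precision/recall/F1 default to 0,
  specificity to 1 (conservative conventions keeping reports total).
* Pixel shuffle requires the channel count divisible by $a^2$; the
  inverse permutation is exact.

## Known limitations

Single-threaded CPU training only — adequate for the desk-scale
experiments the package targets, not for the full 54k-image dataset.
The channel-attention bottleneck is fixed to global average pooling
(no max-pool descriptor). The reconstruction head is wired for the L1
objective only. The exponential loss's margin scale on probabilities is
a package choice; other encodings (e.g. logit margins) would change its
comparison row.
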