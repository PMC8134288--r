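---
title: "Methods: learned ultrasound B-mode rendering at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learned ultrasound B-mode rendering at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interactive ultrasound training simulators must produce realistic B-mode
frames at real-time rates. High-quality physically based renderers (Monte
Carlo ray tracing over anatomical surface models) are too slow for
interactivity, so this package implements the alternative strategy of
*learning* the rendering: run the expensive simulation offline to build a
paired corpus, then train a conditional generative adversarial network
(GAN) that maps a cross-sectional tissue label map `s` — plus a cheaply
derived *integral attenuation map* `a` — directly to a B-mode image.
Inference is a single network forward pass.

`usgan` provides the whole loop at desk scale: a procedural phantom
generator and a simplified reference simulator stand in for the offline
renderer, and all training and evaluation runs on one CPU at reduced image
sizes (64 x 64 polar grids rather than 1000 x 1386 frames).

## Physics carried by the inputs

**Integral attenuation.** Acoustic shadows are a *cumulative* directional
effect: tissue with attenuation coefficient `mu` dims everything below it
along the beam. A convolutional generator with a small receptive field
cannot see the cause of a deep shadow. The attenuation map localizes this
global effect:

    a[z, x] = exp(-sum_{i=0..z} mu[i, x])

computed down each pre-scan-conversion (polar) column with an inclusive
cumulative sum, normalized by the 98th percentile of the image and clipped
to [0, 1], then scan-converted to Cartesian coordinates. Normalization is
per image; clipping makes the map a valid network input (the upper tail
above the 98th percentile carries no shadow information). The cumulative
sum is inclusive — row `z` includes its own attenuation — which is the
repository-wide convention asserted in the tests.

**Geometry.** A convex probe with field-of-view 70 degrees and 15 cm
depth (defaults) images a fan-shaped sector. The virtual apex sits
`probe_radius_cm` behind the skin line (default 4 cm; the probe radius is
a free geometry parameter). Intensity images are scan-converted with
bilinear inverse-mapping interpolation; label maps use nearest-neighbour
sampling so categories never blend. The Cartesian raster is rounded up to
multiples of 16 pixels so frames pass cleanly through four stride-2
stages; the margin lies outside the fan mask `m`.

## The reference simulator (`refsim`)

The offline ray tracer is out of scope; `refsim` is a deliberately
simplified convolutional simulator that reproduces the *statistical*
structure the network must learn — speckle texture, directional bone
shadows, boundary reflections, fan masking:

1. scatterer amplitudes drawn per pixel from a rectified
   `Normal(echo_mean, echo_std)` of the pixel's tissue;
2. convolution with a Gaussian-windowed axial-cosine point spread
   function, evaluated in three depth bands with linearly interpolated
   widths and blended by *source* depth (each scatterer radiates its own
   band's kernel). Kernels are made zero-mean (RF is bandpass) and
   unit-energy so speckle statistics are stationary in depth;
3. boundary reflections: rectified axial impedance contrast, blurred and
   modulated onto the axial carrier, added with a configurable gain;
4. multiplicative shadowing by the *unnormalized* transmission map (the
   physics), while the network input uses the normalized map (the
   training protocol) — both derive from the same integral;
5. per-column envelope via the analytic signal (FFT zero-padded to twice
   the column length so bright shallow echoes do not wrap circularly into
   deep rows);
6. exponential time-gain compensation (default gain compensates the
   background attenuation coefficient), log compression to a 45 dB
   dynamic range, 8-bit quantization, scan conversion, fan masking.

The low-quality variant (for the LSA2H input) scales the PSF widths by a
degradation factor and block-downsamples/nearest-upsamples the compressed
image; factor 1 reproduces the reference renderer exactly, and the same
seed shares the speckle realization.

What the simulator does *not* model — refraction, directional specular
reflections from ray tracing, elevational aggregation, RF-accurate
beamforming — bounds what passing tests show about real data: the GAN
demonstrably learns speckle statistics and attenuation shadows, not the
full artifact repertoire of clinical imaging.

## Phantoms and tissue properties

Phantoms are drawn on the beam-aligned grid (the attenuation integral is
defined per polar column): background soft tissue, liver-like hyperechoic
and muscle-like hypoechoic ellipses, anechoic cysts, and small bone discs
confined to a shallow axial band so their shadows fall inside the image.
The tissue LUT values are plausible rather than calibrated (the
underlying per-tissue acoustic properties in this field are hand-modeled
from literature); `mu` is expressed per axial sample with frequency and
unit conversion folded in, so `exp(-sum(mu))` is dimensionless. Bone
attenuates 75x background — deep shadows; the cyst is exactly anechoic.
Per-record seeds are derived from the master seed by a 32-bit
multiplicative mix, making every record individually reproducible.

## Generator and discriminator

The generator is an encoder-decoder with U-Net skip connections and four
switchable components, each ablatable on its own:

- **concat** — the network inputs, resized to every scale (average
  pooling for continuous maps, nearest-neighbour for one-hot label
  planes), are concatenated to the activations at each intermediate
  layer, preserving location-specific conditioning;
- **small receptive field** — stride-2 4 x 4 encoder convolutions,
  4 downsampling blocks at full scale (46 px receptive field);
  the attenuation input makes a global view unnecessary;
- **texture-friendly decoder (conv)** — even-kernel (4 x 4) transposed
  convolutions avoid checkerboard artifacts, and two extra stride-1
  3 x 3 convolutions per decoder block refine texture;
- **noise injection** — a per-scale Gaussian noise image, scaled by a
  learned per-channel weight (initialized to 0) and added after the skip
  connection, gives the network a stochastic source for speckle.

Leaky ReLU activates the encoder, ReLU the decoder, tanh the output;
nonlinear activations are followed by instance normalization (no affine
parameters). Channel widths double per scale from `base_channels`, capped
at 8x. Exact widths are a free choice; the defaults reproduce the
intended parameter regime and scale down cleanly. Noise is *not* injected
at the bottleneck, and the input-noise variants use a single noise plane.

The discriminator is a patchGAN: three stride-2 4 x 4 convolutions plus a
stride-1 head produce a spatial logit map conditioned on `(image, s, a)`;
each logit judges a local patch. Instance normalization (layers past the
first) couples logits weakly through per-image statistics, so exact patch
locality holds only with normalization disabled — the tests check both.

Variants: `SA2H` (all four components, inputs s + a), `SA2H-att/-concat/
-conv/-noise` (one component removed each; the noise ablation substitutes
an input noise plane), `LSA2H` (adds the low-quality render as input) and
`NSA2H` (replaces it with a noise plane). The two baselines follow the
earlier translation architecture: none of the four components and double
base width, giving the ~4x parameter ratio reported by the harness.

## Objective and training loop

With fan mask `m` applied pixel-wise to the generator output:

    L = L_GAN(G, D) + lambda * E || y - m o G(s, a) ||_1,   lambda = 100

The GAN term is logit-space binary cross-entropy averaged over the patch
logit map (discriminator: mean of the real and fake halves; generator:
the non-saturating form `-log D(fake)` by default, with the saturating
form one flag away). Adam with learning rate 2e-4, beta1 = 0.5,
beta2 = 0.999, batch 4, on-the-fly crops (full-scale 512; desk scale
trains on full 64-px frames). Crops are sampled uniformly among positions
with at least 25% fan coverage so batches are never empty background.
Alternating D/G updates at ratio 1:1. The split utility assigns a seeded
90% train fraction. Everything — split, initialization, crops, noise —
derives from one seed; two runs with the same seed produce identical
histories.

Training length at desk scale (hundreds of steps) is a declared budget,
not a reproduction of the original training schedule, which is not
stated. `SA2H-small`, the configuration used by the package's smoke
experiments, is base 16 / 3 downsampling blocks / 64 px.

## Metrics

- **PSNR** defaults to the linear-peak form `10 log10(255 / MSE)`; the
  conventional `255^2` variant is one flag away and every report records
  which was used. Identical images give an `Inf` sentinel.
- **MAE** is computed inside the fan mask.
- **pchi2** tiles both images into non-overlapping 20 x 20 patches
  (border remainders dropped), takes 50-bin normalized histograms over
  [0, 255] per patch, their chi-squared distance
  `0.5 * sum (hA - hB)^2 / (hA + hB)` (zero-denominator bins skipped),
  and reports the root mean square over patches intersecting the mask.
  Normalizing histograms to frequencies bounds every patch value by 1,
  matching the [0, 1] scale of the spatial error maps.
- **FID** fits Gaussians to image features and evaluates the Frechet
  distance, with the covariance square root computed via the symmetric
  eigendecomposition and negative eigenvalues clipped at zero; a small
  diagonal regularizer guards degenerate covariances. The Inception-v3
  feature space needs external pretrained weights, which are not bundled;
  requesting it raises an explicit error, and the default feature space
  is a seeded random projection of resized images (deterministic,
  training-free). The full-scale crop protocol (512 center crop, four
  299 corner sub-crops) scales all sizes by a common factor in desk mode.

## Numerical choices and degenerate inputs

- Percentile normalization uses R's linear-interpolation quantile
  (type 7); a zero percentile raises a degenerate-input error.
- The L1 loss is averaged over all pixels (out-of-fan pixels contribute
  zero on both sides); masked-objective gradients vanish identically
  outside the fan, which the tests assert through the autodiff engine.
- Logit-space cross-entropy with a softplus clamp at 30 keeps losses
  finite for saturated discriminators.
- Weight initialization is Gaussian (sd 0.02); learned noise weights
  start at 0 so the stochastic path is initially inert, making
  noise-path isolation testable.
- Nearest-neighbour scan conversion rounds half-integers by R's banker's
  rounding; the tests avoid exact ties.

## Problem sizes used by the test-suite experiments

Module tests run on 24-48 px grids. The smoke-training experiment uses
the conditions of the scaled-down study: 200 pairs at 64 px, SA2H-small,
500 steps, seed 1. The directional ablation experiment (SA2H vs SA2H-att)
uses 10 replicates of bone-heavy 48 px phantoms (40 train / 10 held-out
records, 120 steps, base 8) and compares shadow-region pchi2 with 10 px
patches — shadow regions at this scale are thin, and 20 px patches mostly
straddle their borders. These sizes are the package's declared desk-scale
conditions.

## Known limitations

- The reference simulator's realism ceiling bounds the realism of
  everything the GAN learns; no claim is made about clinical images.
- Fully developed speckle dominates the desk-scale frames, so pixel-wise
  losses saturate well above zero; distributional metrics (pchi2, FID)
  carry the texture comparison.
- Single-frame translation only: no temporal consistency across probe
  motion.
- The hand-rolled autodiff engine implements exactly the layers used
  here; it is not a general-purpose framework.
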