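---
title: "Denoising low-dose planar bone scintigraphy: model, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising low-dose planar bone scintigraphy: model, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Planar bone scintigraphy forms images from gamma-photon counts. Shortening
the acquisition time by a factor $f$ scales the expected counts per pixel by
$f$, so a 30% acquisition is a faithful physical proxy for a 30% injected
dose — at the price of Poisson noise whose relative magnitude grows as
$1/\sqrt{f}$. `scintiden` implements a supervised denoiser for this setting:
a convolutional autoencoder trained on (low-dose input, full-dose target)
pairs of the *same* view and session, together with a synthetic phantom
generator that stands in for clinical data and a quantitative evaluation
stack (PSNR, SSIM, per-dose summaries, paired t-tests and TOST equivalence).

## Counting model and the synthetic phantom

The simulator's ground truth is an *activity map*: a smooth, nonnegative
field of expected counts per pixel at the full acquisition time. Anatomy is
procedural (parametric ellipses, arcs and columns, blurred to emulate
collimator response) rather than atlas-based, so the package carries no
external data: a thorax template (spine column with vertebral modulation
plus rib arcs) and a pelvis template (iliac-wing rings, sacrum, pubic arc),
with per-subject geometric jitter and 0–2 random focal lesions drawn from
the subject seed.

Acquisition is pixelwise Poisson with mean `activity * dose_fraction`
(`acquire_counts()`). Low-dose images are produced from the *same*
full-dose acquisition by binomial thinning (`thin_counts()`): each recorded
count is kept with probability $f$. Thinning a Poisson image yields a
Poisson image with mean scaled by $f$, the thinned image is pixelwise
bounded by its parent, and the noise of the pair is correlated — exactly
the "same patient, same session, shorter time" structure of a clinical
shortened-acquisition protocol. An independent re-draw at reduced mean
would get the marginals right but lose that pairing, which is why thinning
is the default construction. `simulate_point_source()` reproduces the
protocol's physical sanity check: totals of a Gaussian point kernel
(σ = 2 px, a collimator-blur stand-in; the detector response is otherwise
unmodeled) acquired at fractions 0.3–1.0 regress through the origin with
slope equal to the full-dose total and $R^2 > 0.999$.

Count levels are calibration-free defaults, since no clinical count levels
are available to the simulator: background 10 counts/pixel and skeletal
uptake 5× background at full dose, which puts full-dose bone pixels near
50 counts (relative noise ~14%, rising to ~26% at $f = 0.3$) — a plausible
static-view regime. Both are configurable; none of the package's
conclusions depend on the exact values, only the qualitative dose trend.

The simulator deliberately omits attenuation, scatter, septal penetration
and tracer kinetics; it emulates counting statistics and anatomy-like
structure only. Tests passing on these phantoms therefore demonstrate that
the pipeline behaves correctly under the stated counting model, not that
the trained weights transfer to clinical images.

## Intensity conventions

On disk, images are 8-bit grayscale PNGs. Each (low, full) pair shares one
linear count scale (`255 / max(full counts)`, recorded in the manifest), so
stored pixel values remain proportional to counts within a pair. For
training and evaluation, `build_pairs()` by default renormalizes every
image to its own display maximum — the standard per-image intensity
normalization of clinical preprocessing, without which low-dose images
would differ from their targets mostly by a global brightness factor $f$
rather than by noise. The display maximum is taken from a lightly smoothed
copy of the image (Gaussian, σ = 1 px; isolated hot pixels clip to 1,
like display windowing): the raw maximum of a photon-count image is an
extreme statistic with roughly 5% run-to-run jitter, which would inject a
random brightness factor — label noise — into every training target,
while the smoothed maximum halves that jitter. The literal
count-proportional reading is available with `renormalize = "none"`.

## The autoencoder

`model_config()` describes the architecture; defaults are two encoder
stages of widths 32 and 64. Each encoder stage applies:

* a **multi-scale feature block**: parallel same-padded 3×3 and 5×5
  convolutions (each to half the stage width), channel concatenation, and a
  1×1 fusion convolution, then Group Normalization and ReLU. Kernels larger
  than 5×5 are excluded to avoid over-smoothing fine skeletal structure.
  The concatenate-then-fuse form gives the two branches an equal channel
  budget at minimal parameter cost.
* **channel attention**: global average pooling, a bottlenecked fully
  connected pathway $C \to C/r \to C$ (reduction $r = 8$, the
  squeeze-excitation convention scaled to these widths) with ReLU and
  sigmoid, and per-channel multiplicative gating. Because the gate sees a
  global pooled descriptor, it also gives the network a handle on overall
  image intensity.
* **strided-convolution downsampling**: 3×3, stride 2, halving both
  spatial dimensions (learnable, in place of max pooling).

A 1×1 convolution halves the channel count at the bottleneck (ReLU
follows). Each decoder stage applies a transposed convolution (kernel 4,
stride 2, padding 1 — chosen so the doubling is exact and checkerboard
artifacts are avoided) and an **efficient residual block**: depthwise 3×3 +
pointwise 1×1 convolutions with Group Normalization and ReLU inside an
identity skip. Decoder widths default to the mirrored encoder widths
(64, 32): since the architecture has no encoder–decoder skip connections,
all reconstruction detail must be synthesized by the decoder, and a
full-width decoder measurably improves reconstruction fidelity within a
short training budget over a thinner one (configurable via
`decoder_widths`). A final 3×3 convolution produces the single-channel output,
mapped to $[0,1]$ by a sigmoid by default (a clamp mode is available; the
sigmoid guarantees the range the metrics assume). Group Normalization
(8 groups) follows every learned convolution except the final one; the
block multiplicities per stage default to one of each and are configurable.
Weights use Kaiming-uniform fan-in initialization from an explicit seed.

All convolution primitives are implemented in C++ (im2col plus BLAS) with
hand-derived backward passes; the whole computation graph is checked
against central finite differences in the test suite (relative error
~1e-9), and each block against direct sliding-window oracles.

## Loss and training

The training objective is the hybrid
$$L = \lambda\, L_{\mathrm{MSE}} + (1-\lambda)\,\bigl(1 - \mathrm{SSIM}(X_{\mathrm{output}}, X_{\mathrm{target}})\bigr),
\qquad \lambda = 0.7,$$
computed on normalized images (`data_range = 1`). The SSIM inside the loss
is the same Gaussian-window implementation as the evaluation metric — one
source of truth — averaged over the valid window positions, with an
analytic gradient derived from the windowed statistics.

Training uses Adam (learning rate $10^{-3}$; $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$ — standard values, since only the
learning rate is protocol-specified), batch size 16, and at most 2000
mini-batch updates. Epochs are reshuffled under per-epoch derived seeds and
the remainder modulo the batch size is randomly excluded each epoch, so
every batch is full. Early stopping uses patience 50 *validation
evaluations*: a baseline evaluation at iteration 0 fixes the initial best,
the validation loss is evaluated every `validate_every` updates (default:
every update, which makes evaluations and updates synonymous and satisfies
both the "validation steps" and the "mini-batch updates" reading of the
protocol), and training halts after 50 consecutive evaluations without
improvement. The returned parameters are those of the *best* validation
loss, not the last iterate, consistent with halting on non-improvement.
For larger runs, `validate_every` and `val_max_pairs` trade validation
cadence against cost without changing the patience semantics.

Splitting is 75/15/10 and, by default, grouped by subject so that no
anatomy appears in two splits; a per-image mode reproduces the ungrouped
reading exactly (largest-remainder rounding: 100 pairs split 75/15/10 to
the item). No stratification by dose fraction or region is applied. No
data augmentation is used: geometric transforms would manufacture
unrealistic anatomy in this modality.

## Metrics and statistics

* **MSE** over all pixels; **PSNR** $= 10\log_{10}(I_{\max}^2/\mathrm{MSE})$
  with $I_{\max} = 255$ for stored 8-bit comparisons (the evaluation
  default) and 1 for normalized images (the loss). Identical images yield
  an infinite PSNR sentinel, excluded from means with a warning.
* **SSIM** with the de-facto standard parameters: Gaussian window 11×11,
  σ = 1.5, $K_1 = 0.01$, $K_2 = 0.03$, population-weighted local moments,
  'valid' windowing (the half-window border is excluded). The
  implementation agrees with an independent literal per-window oracle and
  with scikit-image's reference implementation to <1e-6.
* **Per-dose summaries** group test-set records by dose fraction and
  report mean SSIM/PSNR for (low vs full) and (denoised vs full), with
  *paired* two-sided t-tests per metric — paired because both numbers are
  computed on the same pairs; no multiple-testing correction is applied
  across the seven dose levels. Zero-variance groups yield a
  not-computable marker rather than an error.
* **TOST equivalence**: two one-sided paired t-tests against bounds
  $\pm\delta$ (default 1, one point on a five-point rating scale); the
  overall p-value is the maximum of the two one-sided p-values.

Observer-study machinery (rating capture, intraclass correlation,
two-alternative forced choice) is out of scope; only the numeric paired
procedures are provided.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run a scaled-down analog of the
study: 40 subjects × 2 regions × 2 views × 7 low-dose fractions (1120
pairs) at 64×64 pixels, trained for up to 500 iterations with validation
every 10 updates on a 32-pair subset — sizes chosen so a desktop CPU
reproduces the qualitative result (denoised SSIM above low-dose SSIM at
30–50% dose, monotone dose trends, significant paired improvement at 30%)
in minutes. Unit tests use smaller phantoms (16–32 px) and a narrow model
configuration. The full protocol scale (105 subjects at 256×256, 2000
iterations) is expressible with the same configuration objects.

## Numerical notes and limitations

* All randomness flows through explicit integer seeds via a deterministic
  mixer (`derive_seed()`), exact in double precision; simulate → train →
  evaluate is bit-reproducible on one platform from a single global seed.
* Group Normalization uses $\epsilon = 10^{-5}$; SSIM stability constants
  guard all divisions; the hybrid loss at $\lambda = 1$ has the exact
  analytic MSE gradient.
* The phantom's anatomy is schematic. Absolute SSIM/PSNR values on
  synthetic data are not comparable to clinical values; only their
  ordering and dose trends are meaningful.
* Training on CPU in R is practical at the shipped scales; the
  architecture is intentionally compact (≈163k parameters at the default
  widths).
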