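---
title: "Methods: NIR vein imaging from phantom to disparity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR vein imaging from phantom to disparity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirvein)
```

## The problem

Near-infrared (760–960 nm) light penetrates tissue, and haemoglobin
absorbs it strongly, so subcutaneous veins appear as *dark curvilinear
tubes* on a brighter, unevenly illuminated background in NIR reflectance
images. A vein-imaging rig for robotic venipuncture needs four things from
such images: an enhanced grayscale image, a vein segmentation, a vein
centerline, and — from a rectified stereo pair — a disparity map carrying
depth. This package implements that chain and the synthetic data needed to
test every part of it without access to a clinical dataset.

## Synthetic phantoms: what they emulate, and what they do not

`make_vein_phantom()` draws each vessel as a cubic spline through jittered
waypoints (exercising the curvature that a purely straight tube would
not), rasterises it, and darkens the background multiplicatively with a
Gaussian cross-section profile: at the centerline the intensity is
`background * (1 - contrast)`, and the binary ground-truth mask marks all
pixels within half a vessel width of the curve. The background carries a
linear left-to-right illumination ramp and additive Gaussian noise.
Intensities are floats in [0, 1]; quantisation to 8 bits happens only at
file-writing time, so metric arithmetic in tests is exact.

Default conditions (96×96 px, 3 vessels of width 3–7 px, contrast 0.45,
background 0.65, ramp ±10%, noise σ = 0.02) are chosen to look like a
clean NIR forearm acquisition: vessels clearly darker than tissue but with
realistic width variation and sensor noise. The phantoms do **not**
emulate scattering halos, specular skin reflections, hair, or
depth-dependent blur; a network trained on them says nothing quantitative
about clinical data, which is why all learning results in this package
are treated as *relative* comparisons (transfer vs. random
initialisation, variant A vs. variant B) rather than absolute claims.

`make_stereo_pair()` forward-warps a textured phantom by an integer
disparity field (`left(r, c)` lands on `right(r, c - d)`), resolving
visibility with a rightmost-wins rule, which marks exactly the
geometrically occluded band at each disparity step as invalid. A smooth
random texture (σ-blurred noise) guarantees matchable content in
vessel-free regions. Disparity fields are rounded to whole pixels so the
warp identity is exact; sub-pixel refinement is out of scope.

## Preprocessing

Contrast-limited adaptive histogram equalisation (8×8 tiles, relative
clip limit 2.0) followed by a 5×5 median filter. CLAHE lifts contrast in
the dark vascular regions; the median filter removes impulse noise while
preserving vessel edges better than mean filtering. The CLAHE
implementation is Zuiderveld's (via EBImage); one consequence worth
documenting is that a perfectly constant image maps to a constant image
whose value may shift by a few grey levels (clip redistribution), which
the tests assert explicitly. The median filter uses edge-inclusive
reflected borders and exact float medians. Both parameter sets are
exposed in `preprocess_config()`; the paper-style defaults above are the
common choice for 8-bit medical images.

## Centerline extraction

At a vessel the Hessian of the (Gaussian-smoothed) intensity has one
strongly positive eigenvalue across the dark tube and one near zero along
it. `hessian_eigenvalues()` returns the raw second derivatives at scale
σ, ordered `|λ1| ≤ |λ2|`; the multi-scale response weights them by σ²
before combining scales, so an analytic test (`I = r²` has eigenvalues
{2, 0}) stays exact. The line filter is Frangi's two-eigenvalue
vesselness restricted to dark polarity: zero wherever `λ2 ≤ 0`, otherwise
`exp(-R_B²/2β²)(1 - exp(-S²/2c²))` with `R_B = λ1/λ2`, structureness
`S`, β = 0.5 and `c` defaulting to half the maximum structureness per
scale. Scales {2, 3, 4} px cover the default vessel widths.

The thresholded response is thinned with Zhang–Suen to a unit-width
8-connected skeleton and refined in three steps: spur branches shorter
than `spur_length` hanging off a junction are pruned (the attachment
pixel is also removed when it is a *simple point*, i.e. deletion cannot
split the skeleton locally); endpoints of different components within
`max_gap_distance` are joined by straight rasterised segments
(nearest-first, union-find over components, so joining never splits
anything); finally components smaller than `min_region_area` are
eliminated. This order — prune, join, then eliminate — lets a fragment be
rescued by joining before the area filter sees it. The component count
never increases, which the suite checks on noisy phantoms.

## Segmentation network and self-supervised pretraining

The network keeps the U-Net decoder and skip connections and replaces the
encoder with ResNet18 (7×7 stem, 3×3 max-pool, four stages of two basic
residual blocks, channels 64/64/128/256/512 scaled by a width
multiplier). Each decoder stage 2×-upsamples, concatenates the matching
encoder stage, and applies two 3×3 conv+BN+ReLU blocks; a 1×1 convolution
and sigmoid give per-pixel vein probabilities at input resolution. The
stem takes one channel (NIR is single-channel) and no natural-image
weights are ever used.

There is no deep-learning framework in this package's dependency set, so
layers, forward passes and backpropagation are written out by hand on
compiled im2col convolution, pooling and batch-norm kernels. Every layer's
gradient is validated against central finite differences in the
development tests (relative error ≤ 1e-6), which is the property that
makes the training results trustworthy.

BYOL pretrains the encoder on unlabeled phantoms: two independently
augmented views per image (random crop–resize with area fraction 0.6–1,
horizontal flip p = 0.5, brightness/contrast jitter p = 0.8, Gaussian
blur p = 0.5 — the standard list minus colour-channel operations, which
have no meaning in grayscale); an online network (encoder → projector →
predictor) chases a stop-gradient EMA target (momentum 0.99) of the
encoder+projector. The symmetrised per-pair loss
`2 - 2·cos(q, sg(t))`, averaged over both view orders, lives in [0, 4];
batch normalisation in the projector is what keeps the representation
from collapsing. Three small-batch stabilisations, all standard BYOL
practice, matter a great deal at this scale and are defaults in
`byol_config()`: the learning rate (base 3e-3, Adam) follows a cosine
decay to zero and the EMA momentum is annealed from 0.99 towards 1; the
predictor trains at ten times the base rate, since the asymmetric
predictor must track its optimum faster than the encoder moves; and the
target network is evaluated with its EMA-tracked batch-norm *running*
statistics — at batch size 5, per-batch statistics make the regression
target itself noisy and put a high floor under the attainable loss.
Without these, the 1200-step budget converges for some phantom sets and
plateaus far above the floor for others; with them the final-epoch mean
loss lands between roughly 0.1 and 0.5 across seeds in about six minutes
on one CPU. Batch size is 5 (the reported training regime is ambiguous about
whether "five batches" means batch size or batch count;
`byol_config()` exposes it).

Fine-tuning transfers the pretrained encoder parameters (shape-checked
per layer) into the full U-Net and trains *all* layers — the encoder is
not frozen — with mean binary cross-entropy, recording per-epoch
BCE/IoU/Dice (optionally Hausdorff) on a held-out split and keeping the
best-Dice checkpoint. Both the per-epoch mean batch BCE and the sum of
per-batch average BCEs are logged, since reported training traces use
the latter convention. The learning-benefit claim is deliberately
relative: on the synthetic benchmark a transferred encoder reaches a
target Dice in no more epochs than random initialisation (median over
three seeds). Absolute published metric values are not reproducible
without the original dataset and are not attempted.

## Variable-weight AD-Census stereo matching

The matching cost between left pixel `p` and right candidate `q = p − d`
combines an absolute-difference term and a census term, each normalised
by `ρ(c, λ) = 1 − exp(−c/λ)`:

```
C(p, q) = α·ρ(C_AD, λ_AD) + (1 − α)·ρ(C_C, λ_C)
```

Census uses a 9×7 window, bits ordered row-major with the centre skipped,
bit = 1 iff the neighbour is darker; the cost is the Hamming distance.
λ_AD = 10 and λ_C = 30 on the 0–255 intensity scale. Out-of-frame
candidates take the sentinel cost 1 (the supremum of the combined cost).

The *variable weight* is `α = 1 − exp(−1/h_min)` where `h_min` is the
minimum of the pixel's four cross-arm extensions: near intensity edges
arms are short, `h_min` small, α large, and the AD term dominates; inside
homogeneous regions the census term dominates. (The exponent is read so
that α decreases in `h_min`, the only reading consistent with that
behaviour.) The classic equal-weight matcher is available as
`weight_mode = "fixed"`.

Cross arms extend until a rule fails. The single-threshold rule accepts a
candidate at distance `e` iff `|I(p) − I(p')| < τ` and `e < L`
(defaults L = 17, τ = 20). The two-tier rule uses a generous threshold τ1
near the pixel (`e ≤ L2`) and a tight τ2 in the far tier
(`L2 < e ≤ L1`), and additionally bounds the *consecutive* difference
`|I(p') − I(p'')|` with the tier threshold — so arms stop at edges
instead of stepping across them, yet can grow long in weak texture.
Defaults L1 = 34, L2 = 17, τ1 = 20, τ2 = 6 (the CBCA-literature
convention; none are printed in the source material). The printed
horizontal rule is applied to vertical arms with rows substituted.

Aggregation averages costs over the adaptive cross-based support region —
the union over the pixel's vertical arm of those pixels' own horizontal
arms (horizontal-first), or the transpose — combining the left pixel's
cross with the matched right pixel's cross by per-direction minimum.
Exact pixel counts are propagated, so each pass is a true mean (scale
stability across region sizes); two passes with alternating orientation
by default. Winner-takes-all with ties toward the smaller disparity, then
left-right consistency (the right-view disparity is read out of the same
aggregated volume via `C_R(r,c,d) = C_L(r,c+d,d)`), occlusion filling
with the smaller of the nearest valid row neighbours, and a
validity-aware 3×3 median. The scanline-optimisation stage of the
original full AD-Census pipeline is intentionally absent: only the cost
and aggregation stages are the subject here.

Every compiled stereo kernel is verified against an independent
brute-force enumeration (nested loops, explicit support regions) on
random ≤ 16×16 instances at 1e-12, and the optimized-vs-original
comparison is run on a repetitive-texture benchmark: phantoms dominated
by a sinusoidal stripe pattern whose period (8 px) lies inside the
disparity search range, so cost minima alias. The benchmark statistic is
the mean bad-pixel rate over three seeded phantom instances — averaging
over instances the way multi-image stereo tables average over scenes.

## Metrics

BCE (natural log, predictions clipped at 1e-7), IoU and Dice from the
confusion counts (both-empty masks score 1 by convention; Dice =
2·IoU/(1+IoU) is fuzz-tested), and the symmetric Hausdorff distance.
HD is computed between *boundary* pixel sets (foreground pixels
4-adjacent to background), since HD is the edge-sensitive metric in this
panel; whether full foreground or boundaries were used upstream is
unstated, which affects absolute values but none of the properties tested
here. The fast path uses an exact Euclidean distance transform and is
fuzz-checked against the O(|A||B|) brute force. Disparity maps are scored
by mean absolute error and the bad-pixel percentage above a 2 px
threshold; illuminance uniformity is `min/mean` over the light-receiving
plane. `percent_change()` implements the reduction/increase arithmetic
used in published comparison tables, rounded to two decimals for
reporting.

## Numerical and design choices

* Borders: edge-inclusive symmetric reflection everywhere (median,
  Gaussian derivatives, census), fixed by the package's documented hand
  examples.
* WTA ties break toward the smaller disparity; probability 0.5 is
  foreground; skeleton thresholding is strict (`response > threshold`).
* All randomness flows through R's RNG: a phantom spec, a config seed, or
  a function's `seed` argument fully determines the output, and the suite
  asserts bit-identical reproduction.
* Problem sizes in the test-suite (96×96 phantoms, width-multiplier 0.25
  encoder for the 50-epoch pretraining run; 64×64 and width 0.125 for the
  supervised comparisons) are the package's desk-scale profile: small
  enough to iterate on a laptop CPU, large enough that five 2×
  downsamplings and the skip geometry are all exercised. The full-width
  profile (`width_multiplier = 1`) is the same code.

## Known limitations

* Phantom realism is calibrated only to a qualitative description of NIR
  forearm images; no clinical validation is implied.
* Integer-disparity ground truth and no sub-pixel refinement.
* Rectification is assumed done upstream; camera calibration is out of
  scope.
* The BYOL run at desk scale can collapse partially for degenerate
  augmentation settings (e.g. all augmentations disabled on one image);
  the configuration validator and a two-image minimum guard the obvious
  cases.

## A worked example

```{r example, eval = FALSE}
library(nirvein)

# a stereo phantom with constant disparity 6
st <- make_stereo_pair(stereo_phantom_spec(
  phantom_spec(48, 96, seed = 4, noise_sigma = 0.01), 6,
  texture_amplitude = 0.12))

sm <- match_stereo(st$left, st$right,
                   stereo_params(d_max = 12, L1 = 17, L2 = 8))
disparity_error(sm$disparity, st$disparity + 0 * st$left, st$valid)
```
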