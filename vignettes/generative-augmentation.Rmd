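---
title: "Mask-preserving generative augmentation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-preserving generative augmentation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosynth)
```

## Why augment this way

A segmentation dataset for echocardiography couples each B-mode frame
with pixel-level labels whose exact boundaries are expensive expert
work. Two properties make ordinary generative augmentation risky here:
(i) a conditional generator can only be trained on labeled data, and
(ii) nothing guarantees that a generated image actually matches the
label it was conditioned on — precisely at the myocardial border, where
pixel accuracy matters most.

`echosynth` instead applies *geometry* transforms to the image-label
pair (emulating different acquisition depth, probe tilt, sector width
and ventricle position) and then asks an *unconditional* diffusion model
to fill in only the pixels that the transform exposed — the complement
of the transformed sector support. The labeled pixels are never touched:
the keep mask is warped with the same nearest-neighbour semantics as the
label mask, so a labeled pixel is in the kept region by construction,
and the composite at the final step substitutes the clean input, making
preservation bit-exact. A run-time assertion (`assert_label_safety`)
backs the construction.

## The diffusion model

The forward process corrupts a latent $x_0 \in [-1,1]^d$ over $T$ steps,
$q(x_t \mid x_{t-1}) = \mathcal N(\sqrt{1-\beta_t}\,x_{t-1}, \beta_t I)$,
so that $x_T$ is approximately white noise. We use the squared-cosine
schedule $\bar\alpha_t = f(t)/f(0)$,
$f(t)=\cos^2\!\big(\tfrac{t/T+s}{1+s}\cdot\tfrac\pi2\big)$, $s=0.008$,
$\beta_t = 1-\bar\alpha_t/\bar\alpha_{t-1}$ clipped at $0.999$, and
always store $\bar\alpha_t$ as the running product of $1-\beta_t$ so the
container invariants hold to machine precision.

The reverse model predicts the noise $\hat\epsilon(x_t,t)$ and a
variance-interpolation field $\hat v \in [0,1]$,
$\log\Sigma_\theta = \hat v \log\beta_t + (1-\hat v)\log\tilde\beta_t$,
where $\tilde\beta_t$ is the closed-form posterior variance. Training
minimises the hybrid loss: mean-squared error on the noise plus a small
weighted KL between the closed-form posterior
$q(x_{t-1}\mid x_t,x_0)$ and the predicted reverse Gaussian. Three
choices the source material leaves open:

* **Mean detachment.** In the KL term the predicted mean is treated as a
  constant, so the variational gradient trains the variance only (the
  cited improved-DDPM practice).
* **$t=1$ term.** The posterior variance at $t=1$ is zero (with
  $\bar\alpha_0 := 1$), so the Gaussian KL is undefined there; the
  reference implementation substitutes a discrete decoder likelihood. At
  this package's scale that machinery is not warranted: the variational
  term is simply dropped at $t=1$, and the $t=1$ reverse step returns
  the posterior mean without noise.
* **Weight.** `vlb_weight = 0.001` by default, the hybrid-loss choice of
  the cited reference; it is a config field, not a constant.

Timesteps are drawn by importance sampling with
$p_t \propto \sqrt{\operatorname{mean}(L_t^2)}$ over the last 10
recorded losses per timestep, uniform until every timestep has 10
records, and each draw is weighted by $1/(T p_t)$. Note the consequence
of the squared loss under the root: a timestep with $k$-fold larger loss
is sampled $k$-fold (not $\sqrt k$-fold) more often.

The predictor itself is a small fully-connected network over the
flattened latent concatenated with a sinusoidal time embedding — there
is no deep-learning framework in the target environment, and at phantom
scale (2–4096 pixels) a hand-written MLP with explicit backpropagation
and Adam is both sufficient and fully inspectable. Two training
stabilisers proved necessary for reproducible moments of the generated
distribution and are on by default: an exponential moving average of the
weights (decay 0.999, the returned parameters) and a linear
learning-rate decay to zero. A full-scale configuration (T = 4000,
256×256, U-Net-class predictor) is expressible in `training_config()`
but is explicitly out of scope.

Sampling supports timestep respacing (an evenly spaced subsequence with
recomputed $\beta'$), the standard fast-sampling construction; the
retained forward marginals are unchanged, which the tests check.

## RePaint

At each reverse step $t$ the known region of the current latent is
replaced by a draw from $q(x_{t-1} \mid x_0 = \text{known})$ — the
one-shot form, drawn fresh from the clean image at every visit; a
per-step iterated variant is available behind `noise_known =
"per-step"`. After each block of `jump_length` reverse steps the
composite is re-noised forward by the same number of one-step
transitions and the block is redone `n_resample` times, which
harmonises generated and kept content. At step 0 the kept region is
substituted noise-free, making preservation exact for any predictor —
an invariant the acceptance suite checks bit-for-bit.

One empirical finding worth recording: RePaint is an *approximate*
conditional sampler, and its residual bias depends on the chain
resolution. On an analytically tractable toy problem (a bivariate
Gaussian "two-pixel image", conditioning on pixel 1, repainting pixel
2), even an analytically *exact* predictor leaves the conditional mean
about 2.7 standard errors (of a 2000-draw average) short of the analytic
value on a 50-step chain, whereas on a 200-step chain with
`jump_length = 1, n_resample = 5` the bias is within 0.3 SE. The
acceptance tests therefore use the 50-step chain where the contract is
about marginal moments, and the 200-step chain where it is about
conditional recovery.

## The five augmentations

All parameters are drawn uniformly over their ranges; images are warped
bilinearly, masks and keep masks with nearest-neighbour semantics; the
fixed application order in `combine_transforms` is depth → tilt → width
→ translation.

* **Depth increase** λ ∈ [0,150] px: black rows appended at the bottom,
  frame resized back. The resize is *isotropic* (the sector shrinks
  without distortion) — this is what makes the physical LV area
  invariant (pixel count × both spacings), which the tests verify within
  5% discretization error; spacing picks up the factor (H+λ)/H on both
  axes.
* **Tilt** θ ∈ (−30°, 30°) about the sector tip (top-center fallback if
  geometry is missing); content leaving the frame is cropped.
* **Width** factor ∈ (0.5, 1.5), horizontal scaling about the apex
  column: stretch-and-crop above 1, squeeze-with-black-gaps below 1.
  Column spacing divides by the factor; the resulting anisotropy is
  tracked, not corrected.
* **Translation** by an angle (degrees CCW from image-right) and length
  ∈ (0,50) px, rounded to integer pixel shifts so mask equality is exact
  index arithmetic.
* **Combination**: each of the four independently with probability 0.5.

Draws that would crop away more than 20% of the LV are rejected and
redrawn (at most 20 times) — a threshold of ours, protecting the
protocol's assumption that each emitted sample is still a usable
image-label pair. The augmentation protocol emits, per input, the
original plus five combine→repaint samples (6× dataset growth). A
blackout baseline (identical transforms, repaint region left black)
supports ablations of the repainting itself.

Two further preprocessing utilities exist only for diffusion-training
data: sector narrowing by up to 20° (cut the peripheral scan lines, then
stretch back to full width) to enrich sector-width variety, and
frame-stride subsampling of cine loops with stride redrawn uniformly in
{8..12} at every kept frame.

## The phantom: a stated world

There is no data download; everything is tested against a synthetic
phantom whose ground truth is exact. A sample is a sector (apex near the
top, radius spanning 94% of the frame) containing an ellipse-section LV
cavity (dark) wrapped in a myocardial annulus (bright) over a mid-gray
far field, under unit-mean multiplicative speckle built from squared
smoothed Gaussian noise. Acquisition parameters are drawn from the
published characteristics of the two source datasets — depth
127.8 ± 12.2 mm and angle 65.5 ± 4.0° for the HUNT4-like preset,
151.6 ± 24.5 mm and 75.2 ± 5.8° for the CAMUS-like preset, with EF
distributions 59.1 ± 6.6% and 52.5 ± 12.3% — so the generator emulates
the acquisition variety the augmentations are meant to enlarge. LV
semi-axes default to 36–46 mm (long) and 22–30 mm (short) with a 9 mm
wall, ordinary adult dimensions. The acquisition geometry is drawn
*once* per sample; only the LV pose/size is redrawn when it does not fit
the sector (with progressive shrink), because rejecting geometry draws
would bias the depth distribution (we measured ≈ +8 mm before fixing
this).

Cine sequences model the LV as a 3-D ellipsoid whose volume oscillates
sinusoidally between EDV and ESV = (1−EF)·EDV; the two orthogonal
long-axis cross-sections become the A2C and A4C masks, and ground-truth
volumes come from $\tfrac43\pi abc$.

What a green test does **not** establish: realism of texture (no
point-spread function, no scan conversion, no valves or atrium), realism
of LV shape variation (ellipses only), or segmentation-model behaviour
(nnU-Net training is external; the package only exports its folder
format).

## Volumes, EF and statistics

Simpson biplane: per view, the LV long axis is the principal axis of the
labeled pixel set in millimetre coordinates, the length is the extreme-
projection span, the common L is the mean of the two views, and each of
20 discs takes its diameter as the perpendicular extent of the LV pixels
in its slab, ordered from the wider (basal) end. On analytic prolate-
spheroid diameters the n = 20 disc volume is within 1% of
$\tfrac43\pi abc$; mask discretization adds ~2–4% to individual volumes
but largely cancels in EF, which the phantom pipeline recovers within
0.02. Every A2C cycle is paired with every A4C cycle and the pairwise
EFs averaged; exams where all pairs fail raise a typed pipeline-failure
condition, mirroring clinical feasibility handling.

Statistics: Bland–Altman uses the sample (n−1) standard deviation and
±1.96 limits. The Wilcoxon signed-rank test is two-sided, drops zero
differences, uses the exact distribution for n ≤ 25 without ties and a
tie-corrected normal approximation otherwise (no continuity correction),
with Bonferroni adjustment `m·p` capped at 1. Cohen's κ defines the
both-constant-and-equal case as 1 (and constant-but-different falls out
as 0); group agreement averages all distinct within-group or cross-group
rater pairs. The binomial test is exact, one-sided (greater) by default
with a small-mass two-sided option, since the sidedness used in the
source survey is not stated. Hausdorff distances are classical maxima
over boundary pixels in millimetres (HD95 behind a `percentile`
argument), with the brute-force pairwise oracle in the tests.

## Numerical and interface choices

* Latents live in [−1,1], images in [0,1]; conversion is affine and the
  image-level RePaint wrapper copies kept pixels directly to guarantee
  bit-identity across the float round trip.
* One master seed; every stage and operation derives a child seed by
  hashing a tag string (`derive_seed`), so reruns are byte-identical
  (checked by hashing every artifact of a two-run pipeline).
* Coordinates are 1-based (row, col) with row 1 at top, matching R
  matrix indexing; geometry records the sector apex in the same frame.
* On-disk labels follow the CAMUS dialect {1 = LV, 2 = MYO, 3 = LA};
  label 3 is remapped to background on load because the atrium is out of
  scope (often not fully visible, and depth augmentation would fabricate
  atrial anatomy the labels cannot cover).
* PNG images are written 8-bit (round-trip within 1/255; the `png`
  package has no 16-bit writer) — MetaImage float export is the lossless
  path. NIfTI is not supported: no reader exists in the target
  environment and writing one by hand was out of proportion.

## Known limitations

The MLP predictor cannot produce clinically realistic texture at
256×256; it exists to make the algorithms exercisable and falsifiable at
desk scale. RePaint inference cost grows linearly in
`T · (1 + 2·n_resample)`; the defaults (jump 10, resample 10) follow the
method's reference implementation, not a tuned optimum. The blackout
baseline and the nnU-Net export are plumbing for an external
segmentation study, which this package does not run.
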