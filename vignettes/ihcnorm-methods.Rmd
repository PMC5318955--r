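---
title: "Methods: blind colour deconvolution and inter-batch IHC normalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blind colour deconvolution and inter-batch IHC normalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DAB/hematoxylin IHC staining drifts between staining batches: stain colours
rotate (reagent ageing, yellowing over months), and — when antibody or
detection-kit lots change — the intensity distributions deform nonlinearly.
Quantification pipelines that threshold brown and blue values therefore
produce batch-dependent artefacts unless the images are normalised into a
common colour and intensity frame first. `ihcnorm` fits that normalisation
per batch against a chosen target batch and verifies it quantitatively.

The practical setup the package assumes: each batch contributes a
*reference image* — typically a mosaic of square crops, one per core of a
tissue-microarray (TMA) slice cut from the same block for every batch, so
that the reference images carry near-identical biology and any
distributional difference between them is non-biological.

## Staining darkness

All modelling happens in *staining darkness* (SDA) space,

$$\mathrm{SDA}_c(p) = \max\!\left(0, -\log_{10}
  \frac{\min(I_c(p),\ I_{0,c})}{I_{0,c}}\right),$$

computed per channel $c$ on linearised sRGB intensities (IEC 61966-2-1
decoding, normalised to $[0,1]$). This is an optical-density-like scale; no
Beer–Lambert claim is attached to it — DAB is a scattering chromogen — but
darkness increases monotonically with stain amount, which is all the
deconvolution and quantification require. Numerical choices:

* The inner `min` clamps pixels lighter than the glass to zero darkness,
  making the transform total.
* Zero raw intensities are floored at one grey level (linearised) before
  the logarithm, capping SDA at ≈ 3.5 and preserving ordering.
* `I0` is estimated per channel as the *mode* of the 256-bin raw histogram
  over glass pixels, then linearised: the mode is robust to glass
  artefacts, unlike the maximum-intensity rules used historically. Glass is
  whatever survives outside an Otsu threshold on the per-pixel channel
  minimum, dilated by a disc (radius 5 px at ≈ 0.45 µm/px; both the radius
  and the greyscale domain are configurable since neither is canonical).
* A perfectly uniform image is degenerate for Otsu; it yields the global
  mode with an empty tissue mask and a warning rather than an error, so
  blank control tiles do not abort a pipeline.

The inverse transform re-encodes with rounding; round trips are within one
grey level for pixels at most as bright as the background.

## Blind extraction of the stain axes

Two-stain pixels concentrate near a 2-D cone through the origin of SDA
space. With the pixel matrix $X\ (3 \times n)$ and stain basis
$M = [\mathbf{a}\ \mathbf{b}\ \mathbf{a}\times\mathbf{b}]$, the model is
$X \approx M C$, $C \ge 0$. The third (cross-product) axis is retained
purely as quality control: `plane_quality()` reports the ratio of mean
absolute residual-axis coefficient to mean in-plane coefficient norm, which
should be small for a genuine two-stain image.

Background pixels (SDA norm ≤ 0.015, the same radius used for tissue
segmentation) are excluded from every extraction. Five methods are
provided:

1. **`macenko`** — PCA on the non-background pixels identifies the stain
   plane (explained variance of the first two components is checked and
   typically > 99%). The two principal directions are translated to the
   origin; the first is oriented so the mean pixel projection is positive
   (removing the sign ambiguity before angles are computed). Each pixel's
   in-plane angle to the first direction is computed, and the axes are
   placed at the `angle_quantile` and `1 − angle_quantile` quantiles of
   that distribution (default 0.01). This *controls* the negative
   coefficients: about 1% of training pixels per channel end up slightly
   negative, and those mark negligible contributions that are clipped to
   zero at application time — never during extraction, where they are a
   diagnostic. For rare staining, a smaller quantile (e.g. 0.002) places
   the sparse stain's axis better.
2. **`li-init`** — non-background pixels are clustered into two groups by
   hue, treated circularly (Lloyd iterations on the unit circle with a
   deterministic seeded multi-start). The cluster representative is the
   componentwise *median* RGB of its members (chosen for outlier
   robustness; the historical description of this step leaves the
   representative rule open), converted to SDA and normalised.
3. **`li-init-nmf`** — multiplicative (Lee–Seung) updates for
   $\min \|X - MC\|_F^2$ with $M, C \ge 0$, started from `li-init`;
   columns of $M$ are renormalised to unit length each sweep with the
   scale pushed into $C$. NMF is initialisation-dependent and, even well
   started, tends to settle axes slightly inside the cone.
4. **`snmf`** / 5. **`li-init-snmf`** — sparse NMF,
   $\min \|X - MC\|_F^2 + \lambda\|M\|_F^2 + \eta \sum_j \|C_{\cdot j}\|_1^2$,
   from an NNDSVD start (`snmf`; NNDSVD is the package's reading of the
   otherwise unnamed "standard initialisation" in this literature) or from
   `li-init`.

HEM/DAB labels are assigned by `order_stain_vectors()`: the axis with the
larger red-to-blue component ratio is hematoxylin (a blue-appearing stain
absorbs red), ties broken toward DAB for the larger green component. This
replaces the visual assignment a human would make from the pixel-cloud
plots and makes all extractions invariant to pixel order.

### Tuned constants

* `nmf_tol = 1e-6` (relative change of the relative Frobenius residual),
  `nmf_max_iter = 2000`. The larger budget matters: at a few hundred
  iterations the SNMF axes on ~20k-pixel training sets are still several
  degrees from their converged positions.
* `snmf_sparsity = 0.005`, `snmf_regularisation = 0.01`. The sparsity
  balance of this objective must be tuned per context; on the package's
  synthetic reference conditions larger values measurably drag the
  DAB axis into the pixel cloud (the $\ell_1^2$ column penalty prefers
  smaller total coefficients for mixed pixels, which an inward axis
  provides), so the default is deliberately light. Both are config-exposed
  and carry no claim of universality.
* On synthetic references, `macenko` and `li-init-snmf` recover the
  generating axes to within ~3° and ~0.5° respectively; plain NMF and
  NNDSVD-started SNMF are *not* expected to recover axes reliably — they
  are included to make that comparison reproducible, and their tests
  assert only that they run and satisfy the basis invariants.

## Colour matching and distribution fitting

Deconvolving each batch's images with the batch's *own* basis puts all
batches in one HEM/DAB coefficient frame ("colour matching"). The
"before" condition against which matching is judged imposes the target's
basis on the source batch. When matching alone is insufficient — the
signature is a Q-Q plot curving away from the identity line, roughly an
RMSE above 0.05 — a monotone per-channel fit maps the source batch's
deconvoluted value distribution onto the target's. All four fits operate
on 1000 matched quantile pairs (probabilities $(i-0.5)/n$, order
statistics interpolated linearly — `stats::quantile` type 5; the rule is
fixed and documented because RMSE values depend on it):

* `p99` — pure gain $x \mapsto x \cdot P_{99}(t)/P_{99}(s)$. Included
  because it is in common use; a gain cannot fix a nonlinear deformation
  and can *worsen* the post-matching agreement.
* `quantile` — full empirical-CDF matching through a monotone lookup
  table, linear interpolation, linear extension beyond the observed range,
  floored at zero. Never increases the KS distance to the target.
* `linear` — least squares through the quantile pairs (slope is
  nonnegative because both sequences are sorted), floored at zero.
* `bspline` — penalised B-spline regression of target quantiles on source
  quantiles (100 basis functions, P-spline penalty, smoothing by GCV),
  post-projected onto the monotone cone by isotonic regression, evaluated
  by interpolation with *flat* extrapolation so rare very dark pixels are
  not wildly extrapolated. This is the method of choice for lot-change
  deformations.

Fits are estimated on the training sample (clipped nonnegative
coefficients) and applied in deconvoluted space only, never on raw SDA.
Normalised images are recomposed with the **target** basis — so every
normalised batch shares one colour frame — and the target background; the
residual axis is zeroed at recomposition (it is diagnostic, not stain).

## Quality control

Hold-out discipline: the training sample is a fixed-stride regular sample
of the reference (0.1% by default — ~25,000 pixels of a 100-core mosaic);
QC uses a second regular sample at a half-stride phase, disjoint from the
training grid and equally deterministic. Reports cover three stages
(before matching / after matching / after fitting) × two channels, each
with Q-Q RMSE against the identity line and the exact two-sample KS
statistic (own pooled-ECDF implementation, verified against a brute-force
oracle; p-values are asymptotic).

## Quantification

In the clipped deconvoluted plane: tissue pixels lie outside a disc of
radius 0.015 at the origin; positive pixels additionally have
`dab > dab_threshold` and `dab > dab_over_hem_factor * hem`; for nuclear
markers the nucleus denominator is the union of positive nuclei and blue
nuclei above `hem_nucleus_threshold`. The two thresholds and the factor
are pathologist inputs set *on the target batch only* — the whole point of
normalisation is that they transfer unchanged. Per core:
`LI = 100 · |positive| / |denominator|` and
`QS = (LI/100) · mean(dab over positive)`, i.e. the mean DAB darkness over
the denominator with negative pixels zero-set. QS is reported unitless on
that fraction scale (the convention is stated because several scales
circulate). Cores with under 50 denominator pixels are flagged unreliable
and excluded from distribution comparisons, which are two-sample KS tests
across cores.

## The synthetic generator

`generate_reference()` emulates the reference-mosaic protocol: each tile
holds a centred circular tissue core (the contiguous glass margin realises
the background fraction — speckled i.i.d. glass would defeat the
morphological tissue mask, and real glass is contiguous); pixels inside
the disc are HEM-only, DAB-only or mixed with per-core proportions drawn
from a Dirichlet around the global fractions (concentration 60, giving the
core-to-core LI spread of a heterogeneous TMA); concentrations are
shifted gammas (`0.05 + Gamma(2, 0.25)` for HEM, `0.05 + Gamma(2, 0.30)`
for DAB — right-skewed, bounded away from the background cut-off, peak
darkness ~1.5); the rendered SDA is
$c_h \mathbf{v}_h + c_d \mathbf{v}_d + \varepsilon$ with the default axes
at the commonly published HEM/DAB directions (0.650, 0.704, 0.286) and
(0.268, 0.570, 0.776). Noise is Gaussian in SDA, 0.005 on tissue —
the level implied by ±1–2 grey levels at mid intensity on a calibrated
scanner, since $\sigma_\mathrm{SDA} \approx 0.434\,\sigma_I/I$ — and
0.002 on glass (calibrated background). The default geometry is 100 cores
of 500 × 500 px, ~25 million pixels.

`perturb_batch()` re-renders the *same* draws (same seed; the random
stream never depends on the perturbation, so an identity perturbation is
bit-identical) under in-plane axis rotations (colour drift/yellowing),
monotone per-channel intensity maps (lot changes; the test suite uses
$s \mapsto s + 0.6 s^3$, whose pre-fit Q-Q RMSE ≈ 0.34 matches the
magnitude of a real lot change), and an optional additive tint. This
reproduces in silico exactly the guarantee consecutive TMA slices give in
the laboratory: identical biology, different rendering.

What the generator does **not** emulate: tissue texture, nucleus
morphology, spatial correlation of staining, scanner shading, saturation
nonlinearity, or focus artefacts. Passing tests therefore demonstrate the
statistical machinery — axis recovery, distribution alignment, parameter
transfer — under known ground truth; they do not certify performance on
any particular scanner or protocol, which should be verified per context
with the built-in QC stages.

## Problem sizes and determinism

The test suite runs on scaled-down references (9–100 cores of 40–100 px
tiles, training samples of 4,000–25,000 pixels) chosen so the whole suite
completes in about a minute while every assertion still operates in the
regime where the estimators are stable; the acceptance script uses the
full-scale default geometry. All randomness flows from explicit seeds
(generation restores the caller's RNG state), and regular sampling is
seed-free by construction.

## Known limitations

* Two stains only for `macenko` (a plane has two edges); the SNMF route is
  the natural extension to more stains but is validated here for two.
* Pairwise normalisation to one target batch; no joint multi-batch
  harmonisation.
* The distribution fits assume the reference images of the two batches
  carry the same biology — that is what the common-TMA design provides;
  references sampled from different tissue would confound biology with
  batch effects.
* P99 rescaling is provided for comparison and can degrade results; the
  package reports the degradation rather than hiding it.
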