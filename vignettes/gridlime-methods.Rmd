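---
title: "Local surrogate explanations for patch classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local surrogate explanations for patch classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridlime)
```

## The problem

A convolutional classifier that labels 96x96 H&E histology patches as
"tumor in the central 32x32 window" (class 1) or not (class 0) is a black
box: it outputs probabilities, not reasons. gridlime explains a single
prediction by a local interpretable surrogate. The image is partitioned
into segments (superpixels or grid squares), a distribution of perturbed
images is created by blacking out random subsets of segments, the
classifier is queried on each perturbation, and a linear model of the
chosen class probability is fit on the binary visibility masks. Each
segment's coefficient is its explanation weight: positive favors the
explained class, negative opposes it.

## The surrogate model

Let $z \in \{0,1\}^K$ encode which of the $K$ segments stay visible and
$f(z)$ be the classifier's probability for the explained class on the
correspondingly masked image. The surrogate is the affine model

$$ \hat f(z) = b + \sum_{j=1}^{K} w_j z_j, $$

fit by ordinary least squares on $N$ sampled masks (the first mask is
always all-ones, so the unperturbed prediction is in the fitting set; the
rest are i.i.d. Bernoulli(1/2) per entry). Plain unweighted regression is
the default; the exponential proximity kernel
$\exp(-d^2/\sigma_k^2)$ over cosine distance to the all-ones row, familiar
from the reference LIME implementation, is available behind a flag for
comparability but changes little on these designs. There is no ridge
penalty and no feature selection: a Bernoulli(1/2) design with
$N = 10{,}000$ rows is well conditioned for $K$ up to several hundred, and
every segment weight is reported and plotted. The fit score is the
coefficient of determination on the fitting set, defined as 1 when the
residuals are identically zero.

Two exactness properties anchor the implementation and are enforced by
tests at tolerance 1e-9: any target affine in the mask bits is recovered
coefficient-for-coefficient whenever the design has full column rank, and
for a two-class classifier whose rows sum to one the class-0 weights are
the exact negation of the class-1 weights.

### Choice of $N$ and reproducibility

The perturbed distribution holds 10,000 images by default. At that size
the mean absolute difference between weights of repeated explanations of
the same image (fresh masks, different seeds) sits in the 1e-4 to 1e-3
range — negligible against informative weights, which reach 0.5–0.9 —
while at $N = 100$ the run-to-run variability is an order of magnitude
larger. `stability_check()` measures exactly this quantity, and the
acceptance script recomputes it end to end.

Whether the 10,000 samples include the unperturbed image is a convention;
here row 1 is reserved for it, so $N$ counts it.

## Segmentation

Four backends sit behind one contract (`segment_image()`): labels are
always renumbered to a contiguous `0..k-1` range in row-major
first-occurrence order, so downstream code and serialized outputs are
backend-agnostic and deterministic.

* **squaregrid** (native): the frame is cut into $r \times r$ equal
  blocks. On the canonical 96x96 patch the seven default levels
  9, 16, 36, 64, 144, 256, 576 all divide the frame evenly; for other
  sizes block edges fall at `round(i * dim / r)` (half-up, so edge
  placement never depends on the platform's rounding of ties), keeping
  block sizes within one pixel of each other.
* **fha, slic, quickshift** (delegated to scikit-image through a bundled
  Python helper): the three classical superpixel algorithms. All share
  the Gaussian pre-smoothing width `sigma = 0.8` — the Felzenszwalb
  library default, applied uniformly so the algorithms see the same
  smoothing. Quickshift's remaining defaults (`kernel_size = 5`,
  `max_dist = 10`, `ratio = 0.5`) are not dictated by any convention; they
  were fixed once so that typical 96x96 patches fall in the 20–40
  superpixel range, and they are exposed as ordinary parameters.

### Count matching

Cross-backend comparison is only meaningful at equal segment counts.
Quickshift offers no direct count control, so it is the baseline:
`match_segment_counts()` records its count $k^\*$ and then tunes
Felzenszwalb's `scale` (count decreasing) and SLIC's `n_segments` (count
increasing) by monotone bisection, falling back to a grid scan — executed
as one batched backend call — where the count is non-monotone. Counts move
in jumps, so an exact match can be unattainable in a given range; the
result then carries the closest count and a mismatch flag rather than an
error, and the caller decides. This mirrors practice on real slides, where
only images admitting a common count are used for three-way comparisons.

## Multi-scale square-grid attribution

Single-segmentation explanations inherit the segmenter's arbitrariness:
different parameters give different superpixels and different maps. The
square-grid scheme removes the parameters: the surrogate procedure runs
once per grid level (9 through 576 squares), each level an independent
explanation with freshly sampled masks (level $i$ uses seed
`seed + i - 1`, so levels are independent yet individually reproducible),
and the final heat map is the elementwise sum of the per-level maps.
Coarse levels contribute context, fine levels detail; where levels agree
the weights add constructively. The finest grids' individual squares carry
little signal on their own — a 4x4 block rarely explains a prediction —
which is why the summed map, not any single level, is the product. The sum
is exact and is tested by recomputation from the stored per-level maps.

`average_heatmaps()` provides the complementary cross-backend summary: the
elementwise arithmetic mean of the SLIC, Felzenszwalb and quickshift maps
of the same image.

## Rendering conventions

Attribution maps are drawn with a symmetric diverging scale on
$[-L, +L]$: white at zero, saturated blue at $+L$ (for the explained
class), saturated red at $-L$, linear in RGB between the anchors
(anchors fixed at (255,255,255), (0,0,255), (255,0,0) so renders are
bit-exact), clipping outside. The default $L = 1$ matches probabilities;
`limit_sweep()` re-renders one map at limits from 0.001 to 0.8 — a
log-ish ladder spanning the useful range — because maps with small weights
are nearly white at $L = 1$ and only reveal structure at tighter limits.
Expert annotations overlay in transparent green ((0,200,0) at alpha 0.35);
`comparison_panel()` tiles patch, overlay and named renderings in a single
strip for side-by-side reading.

## Synthetic patches and mock classifiers

The generator (`generate_patch()`) exists so every pipeline stage is
testable without downloading any dataset. It renders the contrasts that
explanations key on, not histology: a noisy pink background
(230,180,200), many small round dark-purple nuclei (90,40,110, radius ~3)
scattered everywhere, and — on class-1 patches — a cluster of enlarged
(radius 7–12) lighter-purple (170,120,180) blobs whose boundaries are
sinusoidally perturbed discs ("less consistently shaped"), whose union is
the annotation mask, and whose anchor lies inside the central window so
the labelling rule always yields 1. Labels follow the patch convention:
class 1 iff any annotated pixel falls in the centered 32x32 window.

What passing tests on this generator do show: the surrogate, masking,
summation, averaging, rendering, seeding and labelling machinery are
correct, and explanations localize where the classifier's true
dependence lies. What they do not show: behavior on real stain variation,
scanner noise, overlapping tissue textures, or a real CNN's decision
surface — the mocks are deterministic and far smoother than a trained
network.

Three mock classifiers cover the test needs:

* `linear_mock_classifier()` — exactly affine in segment visibility;
  the exact-recovery oracle.
* `smooth_mock_classifier()` — affine plus $0.01\sin(2\pi s)$. The
  amplitude 0.01 was fixed once as "small smooth nonlinearity": large
  enough that the surrogate has genuine residuals, small enough that the
  classifier stays near-linear the way a well-approximated CNN is near its
  operating point. This is the stability test bed.
* `tumor_detector_classifier()` — probability depends only on the count
  of visible annotated pixels in the central window,
  $p_1 = \mathrm{logit}^{-1}(\beta(v/1024 - 1/2))$ with steepness
  $\beta = 8$ by default: smooth, monotone, and provably indifferent to
  segments disjoint from the annotation, which is what the localization
  property tests exploit.

## Numerical and design choices

* **Seeding.** Every random draw goes through a locally seeded generator
  that restores the caller's RNG state; nothing touches global state.
  Identical inputs and seeds reproduce explanations bit-for-bit.
* **Perturbation law.** Bernoulli(1/2) per segment maximizes design
  information for the linear fit; the replacement color is black, exposed
  as the masking convention rather than a parameter sweep.
* **Singular designs** (e.g. duplicated segment columns) raise an error
  naming the collinear columns instead of silently pseudo-inverting.
* **Degenerate inputs.** Constant targets fit to zero weights with score
  1; all-zero mask rows take cosine distance 1 by convention; a grid side
  larger than the image, a non-perfect-square count, or asymmetric render
  limits are rejected as parameter errors.
* **Problem sizes in tests.** Exactness properties run at full published
  scale where cheap (10,000-sample designs, all seven grid levels at
  $N = 700$, 3 repeats at $N = 10{,}000$ for stability); localization uses
  $N = 400$ per trial over 50 seeded patches, sizes at which the measured
  properties are already stable.
* **16-bit segment-map export** uses TIFF (exact round trip) alongside
  integer CSV; the installed PNG writers here are 8-bit only.
* **Architecture counting.** The custom reference CNN's convolutions are
  counted under valid padding — the only reading consistent with its
  published total of 1,661,186 trainable weights, which thereby
  cross-checks the transcription. The VGG19 variant's published list jumps
  from the last pooling stage (3x3x512) straight to a 1-unit sigmoid
  head; a flatten would imply a 4,609-parameter head and contradict the
  published 20,024,897 total, while global average pooling to a 512-vector
  gives exactly 513 head parameters and matches it, so that reading is
  adopted.

## Known limitations

Black-out masking conflates "segment hidden" with "segment black": a
classifier genuinely attending to black regions is not identifiable by
this perturbation. Superpixel backends require a Python with scikit-image
on the PATH; squaregrid never does. Exact count matching is not always
attainable (counts jump), and the mismatch flag must be honored. The
surrogate is local: weights describe the classifier near the given image
under the masking distribution, not globally. Synthetic patches make no
claim of histological realism; conclusions about real WSI data require
real data and a real model behind the adapter contract.
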