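---
title: "Screening APROP from fundus images: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening APROP from fundus images: models, parameters, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ropscreen` screens a single posterior-pole fundus photograph of a
premature infant for Aggressive Posterior Retinopathy of Prematurity
(APROP). This vignette documents the science behind each stage: the model
assumptions, the tunable parameters and their defaults, what the synthetic
validation does and does not establish, and the numerical choices that a
reader reproducing the pipeline needs to know.

## The screening problem

APROP manifests as abnormally tortuous, densely branching vessels near the
optic disc (OD). Two quantities carry the signal:

* **Tortuosity index `T`** — per vessel segment, the ratio of arc length
  to chord length (straight-line distance between its endpoints). A
  perfectly straight segment scores exactly 1; every curved segment scores
  more. Per image and region, `T` is summarized as the mean of the top
  quartile of segment tortuosities, which emphasizes the most twisted
  vessels without letting a single segment dominate.
* **Segment count `S`** — the number of vessel segments (branch-to-branch
  or branch-to-end skeleton chains) in a region, a proxy for arborization.

Both are computed inside OD-anchored regions (DR1 < 4 OD radii,
EDR1 < 6 r, DR2 the 4-8 r annulus) so that eyes photographed at different
magnifications remain comparable. EDR1 exists because vessels arch near
the DR1 boundary; extending the region to 6 r keeps those arches from
inflating `T` of an otherwise healthy eye. DR2 features are computed and
reported for inspection of peripheral arborization but never enter the
classifier, whose job is strictly the *posterior* pathology.

## Pipeline stages and their parameters

### Preprocessing

The illuminated field is segmented from the channel-mean image after a
contrast stretch between its 1st and 99th percentiles. The global
threshold is Otsu's, computed over non-saturated pixels only: the border
ring clipped at the top of the stretched range (>= 250 of 255) would
otherwise dominate the histogram and pull the split to
interior-versus-ring rather than background-versus-field. After hole
filling and largest-component selection the mask is eroded by
`eye_margin` (default 5 px, about the oriented-blur kernel radius), so
that later convolutions never mix ring values into field pixels.

The OD is masked as the circle through the annotated major-axis endpoints.
The pipeline enlarges this mask by `od_margin` (default 8 px, roughly the
blur radius plus the disc's soft edge): the bright disc rim leaves a
ring-shaped artifact in any background-subtraction vesselness image, and
the disc *boundary* — not just its interior — must stay out of the feature
support. Highly tortuous "vessels" hugging the disc rim in a phantom with
perfectly straight vessels were traced to exactly this artifact.

The analysis channel is chosen by a mean/variance rule over field pixels:
channels with mean <= 64 (the bottom quartile of the 8-bit range, typically
the blue channel of a fundus photograph) are excluded, and the survivor
with the least variance — the most uniformly illuminated — is used. Ties
resolve green, blue, red; if nothing passes the mean rule, the brightest
channel is used with a warning.

### Segmentation

Three backends produce a binary vessel network; all are restricted to the
field mask minus the OD disc.

*Morphology (default).* The channel is blurred with the mean of 12
uniform line kernels (length `blur_len` = 9 px, orientations at 15°) and
subtracted from the blur; dark vessels become bright ridges. Since the
mean of 12 convolutions equals one convolution with the mean kernel, this
costs a single 2-d convolution. The vesselness image is thresholded by
maximizing the sum of background- and foreground-quadrant second-order
entropies of its 256 x 256 gray-level co-occurrence matrix (symmetric,
unit horizontal + vertical offsets, field pixels only, log base 2, with
0 log 0 = 0). The implementation sweeps all 255 candidate thresholds with
2-d cumulative sums; the unit tests verify it against a literal
brute-force maximization.

*Matched filter.* Twelve zero-mean kernels with Gaussian cross profile
(`mf_sigma` = 2 px, length 9 px — the classical defaults for this filter
family) at 15° steps; per-pixel maximum response; Otsu threshold over
field pixels. Kernels are generated analytically in rotated coordinates,
so the 0° and 90° kernels are exact transposes.

*Scale space.* For kernel sizes 3, 5, 7, 9, 11 (sigma = size/6, so the
kernel truncates near 3 sigma): Gaussian blur, 3 x 3 Laplacian (positive
on dark vessels), an adaptive 3 x 3 median filter applied only where a
pixel is a strict local extremum (impulse detection), Otsu threshold, and
removal of components below `island_min` = 20 px. The final network keeps
pixels that are foreground at >= 3 of the 5 scales, which suppresses both
single-scale noise and diffuse choroidal structure.

### Skeleton analysis

The network is thinned with Zhang-Suen iterations plus two cleanup passes:
removal of residual 2 x 2 blocks (deleting only pixels whose local
crossing number allows it), and removal of orthogonal "staircase" detour
pixels whose two neighbors are mutually diagonal. The second pass matters
quantitatively: an 8-connected chain that takes two orthogonal steps where
one diagonal suffices overstates that stretch of arc length by a factor
sqrt(2), and the tortuosity index inherits the bias on oblique curves.

Critical points use the crossing number (number of distinct arms entering
a pixel): end point = one neighbor, branch point = three or more arms. A
plain neighbor-count rule would misread staircase corners — where a
diagonal and an orthogonal neighbor touch each other — as junctions.
Splitting deletes each branch point's 3 x 3 neighborhood (otherwise
diagonally adjacent arm tips remain 8-connected around the junction and
the arms do not separate); every remaining component is a simple path or a
loop and becomes one ordered segment. Loops are traversed once and
flagged; they receive the configured tortuosity cap (`loop_cap` = 10)
because a loop is clinically highly tortuous but has no finite arc/chord
ratio.

Terminal spurs shorter than `spur_len` = 10 px — skeletonization
artifacts, per the screening protocol — are removed, the skeleton is
re-thinned (this fuses the L/T-shaped junction remnants so collinear arms
merge), and critical points are recomputed. Because the re-thin can itself
expose a fresh short terminal, pruning repeats until none remains (bounded
by `spur_passes`, default 8; set 1 for a single cycle) — the contract is a
skeleton devoid of spurs, not a fixed number of passes. Isolated short
components are *not* spurs
(they are whole vessels, not branches off a junction) and are left to the
area threshold. Finally, segments shorter than `area_min` = 10 px are
dropped before feature computation, for all three backends: tiny chains
carry no tortuosity information (their arc/chord is raster quantization)
and mostly arise from sensor noise. The 10-px default deliberately equals
the spur scale.

`arc_len` uses Euclidean steps (1 orthogonal, sqrt(2) diagonal), which
guarantees `arc >= chord` and hence `T >= 1` structurally. The raw pixel
count `lambda` is kept alongside and drives the length thresholds. An
alternative "literal" tortuosity mode (pixel count / squared chord) is
available behind a flag for comparison; it is not dimensionless, is not
bounded by 1, and is not used by the classifier.

### Classification

A pooled-covariance linear discriminant with equal priors and symmetric
0/1 loss is fitted on `(T, S)` per region. Features are z-scored with
training-fold statistics — `T` is of order 1 while `S` reaches hundreds,
and the discriminant should not be an `S`-only rule by accident of units.
If the pooled covariance is singular, a ridge of `1e-6 x trace` is added.
Validation is leave-one-out; a fold left with a single class counts as an
error. The two-region fusion declares an eye healthy only when both DR1
and EDR1 agree; a missing region label falls back to APROP. The rule is
deliberately asymmetric: in screening, a false positive costs a specialist
review, a false negative can cost vision within days.

## The synthetic-fundus generator

No public dataset covers this population, so validation runs on phantoms
with analytic ground truth. Each phantom is a circular illuminated field
(saturated ring of 10 px, near-black exterior), a bright OD disc, and a
vessel tree of radial trunks leaving the OD rim, each centerline a
straight ray perturbed by a sinusoid normal to its path:
amplitude `tortuosity_amp` (px) and frequency `tortuosity_freq`
(cycles / 100 px of arc) control tortuosity with a closed-form arc/chord
oracle evaluated on the continuous curve *before* rasterization, so raster
quantization cannot contaminate the reference values. Branches spawn at
`branch_prob` per px of arc (up to two generations), vessels render with a
Gaussian cross-section (`vessel_width` = 3 px, intensity dip 60 gray
levels in green), and additive Gaussian sensor noise (`noise_sd` = 3) is
applied per channel.

Channel statistics mimic real fundus photographs: green (background 95)
carries the vessel contrast; red (background 140) is brightest but carries
a smooth radial illumination falloff, so the least-variance selection rule
discards it exactly as it does on clinical images; blue (40) fails the
mean rule. Rendering the full 60-level dip into a flat red channel
would invert the selection logic, because in a phantom — unlike a real
photograph — vessel contrast is the only variance source.

Class presets encode the two regimes: *healthy* — amplitude 1 px,
frequency 1.5, branch probability 0.02/px, vessels reaching 8 OD radii
(a maturing, well-vascularized retina); *aprop* — amplitude 5 px,
frequency 2.5, branch probability 0.06/px concentrated within 6 OD radii,
vessels reaching only 6 r (posterior concentration with capillary
non-perfusion beyond). These values are calibration choices — the clinical
literature describes APROP vessels only qualitatively — fixed once when
the generator was designed. Default cohort sizes (15 healthy / 21 APROP)
mirror the screening study the package emulates.

What phantoms do *not* model: choroidal texture, laser scars, optic-disc
pallor variation, non-circular discs, motion blur, and infant-to-infant
variability of vascular maturity beyond the two presets. A passing
synthetic suite therefore demonstrates the pipeline's internal
correctness and its sensitivity to the geometric quantities it claims to
measure — not clinical performance.

## Numerical choices and degenerate inputs

* Coordinates are (row, column), 1-based; masks are logical matrices.
* Percentiles use linear interpolation (R's default type-7 quantile); the
  top-quartile mean takes all values at or above the 75th percentile.
* The GLCM threshold candidates are gray levels 0-254; candidates whose
  background or foreground quadrant is empty are skipped; a constant image
  is a degenerate-input error.
* Otsu thresholds use 256-bin histograms over the masked support.
* A constant matched-filter response yields an empty network with a
  warning, not an error; an image with no intensity contrast fails the eye
  mask with a degenerate-input error and the image is skipped and listed.
* Chain arc lengths use Freeman weights (1, sqrt 2) in all pipeline
  features. For comparisons against *continuous* curve lengths (generator
  ground truth) the package exposes minimax-calibrated weights
  (0.960/1.358, error <= 4% at any line orientation); Freeman weights
  would show their known +8% worst-case quantization bias at 22.5°, which
  is a property of the estimator, not of the generator.
* Per-phantom seeds in a cohort are drawn from the master seed by
  `sample.int`, so any cohort is reproducible from one integer.

## Validation problem sizes

The test suite validates stage contracts on small rasters and phantoms of
320-448 px, and the end-to-end claims on the full default geometry:
640 x 640 px phantoms, OD radius 32 px, cohorts of 15 + 21. The
entropy-threshold oracle check runs 50 random 64 x 64 images against
brute-force maximization; the voting contract is verified pixelwise on 10
full-size phantoms; parameter-recovery grids use 20 phantoms per level at
448 px with per-phantom seeds shared across levels, so that level
differences reflect the varied parameter rather than tree-topology luck.

## Known limitations

* Shallow-angle vessel forks can render as a single merged ridge for a few
  pixels, so the skeleton occasionally bends through a fork instead of
  branching there; the resulting V-shaped chains inflate the tortuosity
  baseline of *straight*-vessel phantoms to about 1.1-1.25 in the top
  quartile. The effect is independent of the perturbation amplitude only
  to first order, which is why parameter-recovery checks share seeds
  across grid levels.
* The entropy threshold admits isolated salt-noise pixels; these become 1-2 px
  skeleton fragments that the segment-length thresholds remove, but they
  do inflate the raw network's false-positive pixel count.
* Loops receive a fixed tortuosity cap rather than a measured value; eyes
  whose pathology manifests mainly as vessel loops are flagged through the
  cap, not quantified.
* The classifier is a linear discriminant on two features; it is the
  screening rule of the emulated protocol, not a state-of-the-art
  classifier, and no probability calibration is attempted.
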