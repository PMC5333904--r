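---
title: "Intensity standardisation of T1-weighted MR volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity standardisation of T1-weighted MR volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mristand)
```

## The problem

Intensity-based analysis of T1-weighted brain MRI — thresholding, colour-coded
manual delineation, intensity-driven segmentation — assumes that the same
tissue is displayed at the same intensity in every subject. Even bias-field
corrected MP2RAGE uniform images violate this: the intensity scale of each
scan carries residual interscan variation of unknown origin, so grey matter
(GM) that sits at level 1800 in one subject may sit at 2050 in another.
Standardisation remaps each *target* image's intensities onto the scale of a
chosen *reference* image. It is a 1-D intensity remapping, entirely distinct
from spatial bias-field correction, and it must walk a line: remove
technical scale differences while leaving biologically meaningful
differences (atrophy, tissue composition, T1 shifts that carry volume
information) intact.

This package implements five standardisation techniques and the evaluation
protocol for deciding which of them walks that line, exercised end-to-end on
synthetic phantoms whose ground truth is known exactly.

## The five transforms

All five produce a monotone mapping `f : [0, 4095] -> [0, 4095]` (the
nominal 12-bit scale is configurable). Volumes are floats internally; the
integer scale is a storage convention, and premature rounding would corrupt
the cumulative-distribution arithmetic below.

**PHM — piecewise linear histogram matching.** Skull-stripped T1-weighted
MP2RAGE histograms are multimodal with distinct GM and WM peaks. PHM detects
the GM and WM histogram modes of target and reference within fixed windows
((1000, 2500) and (3000, 3500)) and interpolates linearly between the
anchors (0,0), (GM\_t, GM\_r), (WM\_t, WM\_r), (4095, 4095). The transform
bends at the two mode anchors — i.e. exactly at the most frequent
intensities, where the bend introduces artificial contrast.

**NHM — non-linear (spline) histogram matching.** The smoothed variant: an
interpolating cubic spline through the same mode anchors plus
identity-diagonal points at 1 and 4094 that prevent overshoot near the ends.
The mapping has a continuous first derivative; monotonicity is verified on a
dense grid and violations are reported and clamped.

**CHM — cumulative histogram matching.** Percentile matching carried to the
extreme: the intensity range is split into 1024 equal classes and each class
is assigned the reference level whose relative cumulative frequency is
closest to the class's target cumulative frequency (ties to the lowest
level; the lookup table is forced non-decreasing). By construction this
imposes the reference's voxel-count structure — including its GM/WM volume
ratio — onto every target.

**RLS — ROI-based linear standardisation.** A single line through two
points: the median intensities of a deep-GM ROI (the hypothalamus) and a
surrounding-WM ROI, in target and reference. ROIs are cleaned against the
tissue segmentation before the medians are taken; the line is applied
globally and clamped.

**SPS — segmentation-based piecewise linear standardisation.** Piecewise
linear through (0,0), the three tissue-mean anchors (CSF, GM, WM from a
3-class segmentation of each image) and (4095,4095) — a tissue-specific
scaling informed by spatial as well as intensity information. Tissue means
are used rather than medians because mean estimates of the tissue classes
are more homogeneous across subjects (between-subject SDs around 75.9 for
GM, 58.5 for WM, 130.9 for CSF on this scale).

## Histogram machinery

The shared substrate is a unit-bin histogram over the declared range
(a value `v` counts in bin `floor(v)`), its robust smoothing, and its
cumulative distribution.

Smoothing is robust locally weighted quadratic regression ("robust loess"):
tricube kernel, window equal to 1% of the intensity levels (41 bins on a
12-bit range), five bisquare reweighting iterations, followed by cubic-spline
parameterisation. Two numerical choices matter and are deliberate:

* **The window is a fraction of all intensity levels of the declared range,
  not of the occupied bins.** Tying the window to occupied bins makes the
  effective bandwidth depend on how many empty bins a particular histogram
  happens to have, which roughly halved the window (and doubled the
  mode-localisation noise) for two-tissue calibration histograms.
* **Bisquare residuals are standardised by the local Poisson scale
  `sqrt(fitted)`**, with the robustness scale estimated over occupied bins.
  A histogram's counts span orders of magnitude; on the raw residual scale
  the MAD is set by near-empty tail bins, and ordinary bisquare reweighting
  then treats the unavoidable counting noise at tall tissue peaks as
  outliers (measured effect: mode error grows instead of shrinking with
  image size). Standardising by the Poisson scale restores the intended
  behaviour — downweight isolated spikes, keep peak-region noise.

Mode detection takes, per window, the intensity of the highest local maximum
of the spline-parameterised smoothed density (ties to the lower intensity; a
window whose mass sits at a single level returns that level; a window with
no interior maximum is an error). A density's *second*-derivative zeros are
inflection points, not peaks; peaks are first-derivative zero-crossings of
the density — equivalently second-derivative zero-crossings of the
*cumulative* curve, which is available behind `detect_modes(from = "cdf")`.
Both routes agree on unimodal windows.

## Segmentation

Three-class fuzzy c-means on voxel intensities stands in for the original
adaptive fuzzy segmentation used with this kind of data; the adaptive gain
field is omitted because MP2RAGE uniform images are already bias-field
corrected, which leaves plain intensity clustering. Initialisation is
deterministic (centroids at the 10th/50th/90th percentiles), convergence is
centroid movement below 1e-3 (cap 200 iterations, reported if hit), and an
optional 6-neighbour membership smoothing (default off — the phantoms have
no spatially correlated noise for it to fix) regularises real data. The
whole procedure is affine-equivariant: mapping intensities by `m*I + n`
maps the centroids identically and leaves hard labels unchanged, which is
what lets a linear standardisation pass through re-segmentation untouched.
Background is defined as exact-zero voxels (the skull-stripped convention);
all pipeline operations preserve it.

## The phantom generator

Phantoms are nested ellipsoids — CSF shell, GM ribbon, WM core — plus a
small central GM sphere ("hypothalamus", default radius 8 voxels, about
2100 voxels: deliberately at the lower limit of what yields a reliable ROI
median) wrapped in a WM shell, so ROI-based standardisation always has a
pure deep-GM/WM anchor pair. Tissue intensities are Gaussian per tissue:
means 600/1907/3246 (CSF/GM/WM; the GM and WM values are the cohort-typical
medians on this scale, the CSF mean is a design choice placed well below
the GM mode window), SDs 130.9/75.9/58.5. Gaussian rather than Rician noise
is used because tissue histograms in this regime are approximately Gaussian
and magnitude-MR noise modelling is out of scope. Default tissue fractions
are CSF 0.40 / GM 0.34 / WM 0.26 of the brain; CSF is somewhat exaggerated
versus real anatomy so that no tissue peak concentrates more than ~2/1024
of the brain's voxels on a single intensity level — the regime in which
1024-class cumulative matching can equalise distributions to its nominal
resolution.

Distortions (what standardisation must undo) form a monotone menu: global
offset, linear `m*I + n`, tissue-wise piecewise linear, and smooth monotone
cubic. The menu is a superset of plausible interscan effects, not a claim
about any particular scanner. Distortions and transforms clamp to the
declared range; background voxels are never moved.

The cohort generator wires phantoms into a study design: `n` subjects with
ages, a GM fraction that declines linearly with age (slope -0.003/year with
small per-subject jitter, giving an age-GM-volume correlation near -0.9 —
imposed deliberately strongly so that its loss under a standardisation
method is unambiguous), WM taking up the geometric difference, per-subject
random linear distortions (slope 0.9–1.1, offset ±150), and one
representative mid-composition reference. `extreme_targets = TRUE` draws
ages from the outer 30% tails only, mirroring the practice of evaluating
standardisation on targets with extreme tissue intensities/compositions.

## Evaluation protocol

Four levels, from histograms down to biology:

1. **Histogram comparison** — average and maximum absolute error between
   tissue-specific cumulative distributions of target and reference over
   their shared intensity range (cumulative rather than plain histograms,
   because methods that produce empty levels or pile-ups would otherwise be
   unfairly penalised). Paired across targets with two-tailed Wilcoxon
   signed-rank tests: zero differences dropped, tie-corrected normal
   approximation, *no* continuity correction, effect size `r = Z/sqrt(N)`
   with `N = 2n` — the only convention that saturates at `|Z| = 3.92` for
   20 one-signed pairs, which pins it exactly.
2. **Average image intensity** — mean absolute voxelwise difference between
   reference and target over voxels labelled as the tissue in *both*
   segmentations.
3. **Local image intensity** — the intensity of the GM/WM boundary around
   the hypothalamus. On real images a rater finds it by sliding the white
   point of a three-colour transfer function (red–white–blue over (0, 4000),
   white at 60% for the reference); on phantoms an automated surrogate takes
   the median intensity of face-adjacent GM/WM interface voxels. Its
   between-subject SD before vs after standardisation is compared with the
   Pitman–Morgan test for correlated variances (`t = r*sqrt(n-2)/sqrt(1-r^2)`
   with `r = cor(x+y, x-y)`, df = n-2); rater test–retest reliability uses
   ICC(3,1) (two-way mixed, consistency, single measures — the two runs are
   the same rater).
4. **Maintenance of biological variation** — Pearson correlation between
   whole-brain tissue volumes (from re-segmentation) and age, before vs
   after standardisation, compared with Steiger's Z for dependent
   correlations sharing one variable (Fisher z, pooled-r covariance), with
   Cohen's `q = |z(r1) - z(r2)|` graded 0.10/0.30/0.50. A significant change
   means the method destroyed biological signal — the characteristic failure
   of CHM, which imposes the reference's GM/WM ratio on every target.

No multiple-testing correction is applied anywhere: the protocol has no
global hypothesis whose alpha would accumulate, and each comparison is
reported with its effect size.

## Problem sizes and seeds

The test and acceptance runs use phantom sizes chosen per question:

* 64³ (≈73k brain voxels) for pipeline and recovery checks, where the
  assertions are exact (1e-6/1e-9) and size is irrelevant;
* 256³ two-tissue calibration phantoms (≈3M GM voxels) for mode-localisation
  accuracy, matching the ~0.7mm whole-head acquisitions the method is meant
  for — mode noise is sampling-limited and scales as `1/sqrt(n)`, so small
  phantoms cannot attest a ±5-level claim;
* 128³ for the CHM matching-resolution check, where the binding term is the
  Poisson fluctuation of the reference's densest intensity level;
* 32³ cohorts (20 subjects, 100 replicates) for the correlation-maintenance
  power check, where only volumes and medians matter.

All randomness flows from named integer seeds; phantom label maps depend
only on geometry, never on the seed.

## Known limitations

The phantoms emulate multimodal histograms, tissue geometry, a deep-GM ROI
pair and global intensity distortions. They do **not** emulate cortical
folding, partial-volume voxels, spatially varying bias fields, Rician noise,
or rater behaviour; passing tests show that the algorithms are implemented
correctly and behave as designed under controlled distortions, not that any
method is adequate for a particular real dataset. Registration is out of
scope throughout: every multi-image operation requires grid-aligned inputs
and refuses anything else. The boundary-intensity surrogate replaces a human
rater with an interface-median; it reproduces the *direction* of
variance-reduction findings, not rater-scale numbers.
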