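---
title: "Receptive-field modelling on synthetic cortex: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptive-field modelling on synthetic cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(visurf)
```

## What this package models

`visurf` implements the analysis chain used to compare visual receptive-field
properties between a single patient and a control group when only one
cerebral hemisphere contributes to vision (hemispherectomy, hence complete
hemianopia): population receptive field (pRF) mapping from stimulus-driven
BOLD signals, connective field (CF) mapping from both stimulus-driven and
resting-state signals, and a statistics layer that contrasts one case
against a set of controls. Because patient fMRI data of this kind are not
publicly deposited, the package ships a synthetic-cortex generator that
produces data with known ground truth; every fitting stage is validated by
parameter recovery against that truth.

## The forward models

**pRF.** A vertex's receptive field is an isotropic 2D Gaussian in visual
space with centre $(x_0, y_0)$ and size $\sigma$ (degrees of visual angle).
Its response drive at frame $t$ is the pixel-area-weighted overlap

$$d(t) = \sum_{x,y} \exp\!\left(-\frac{(x-x_0)^2+(y-y_0)^2}{2\sigma^2}\right) S(t,x,y)\, a,$$

with $S$ the binary stimulus aperture and $a$ the pixel area. The predicted
BOLD series is $d$ convolved with a two-gamma haemodynamic response function
and fitted to the data by amplitude-plus-baseline regression; variance
explained (VE) is the squared correlation, with amplitude constrained
nonnegative (negative-going pRFs are out of scope).

**Mirrored-bilateral pRF.** To probe ipsilateral visual-field responses the
drive is the sum of two equal-size, equal-amplitude Gaussians, the second
mirrored about the horizontal meridian $(x_0, -y_0)$ or the vertical
meridian $(-x_0, y_0)$. Sharing size and amplitude keeps the parameter
count identical to the unilateral model, so the three models compare
directly on VE with no complexity penalty. Equal amplitude for the two
lobes is a modelling choice made precisely to preserve that parameter-count
equality.

**CF.** A target vertex samples the V1 source region through a Gaussian
kernel over geodesic cortical distance, $w(v) = \exp(-d(v)^2 / 2\sigma_{mm}^2)$,
with $\sigma_{mm} = 0$ the delta kernel. Geodesic distance is shortest-path
length over the ROI's mesh edge graph with Euclidean edge weights (Dijkstra
via igraph) — the standard approximation at these mesh resolutions, and one
that is easy to validate against an all-pairs oracle. CF eccentricity is
*inherited* from the pRF eccentricity of the winning centre vertex, never
re-fit. The same fitting engine serves active-state (AS) and resting-state
(RS) runs; only the input series differ.

## The stimulus

The canonical retinotopy cycle is 192 s of a bar sweeping in eight motion
directions (1.5-s steps, 16 frames per sweep), with the final 12 s of each
diagonal sweep replaced by mean-luminance blanks — four disjoint 12-s blank
periods per cycle. Which diagonals are blanked, and the sweep order itself,
are not recoverable from the published description; the package adopts the
convention of alternating cardinal/diagonal directions
(0°, 45°, …, 315°) and blanking each diagonal sweep's final third. This is
explicitly a convention: under a linear model only aperture *coverage*
affects the fitted parameters, so sweep order is configurable and immaterial
to recovery.

Two geometries are supported: the control geometry (10.21-deg radius,
2.75-deg bar — the default, since all analyses cap eccentricity at 10.2 deg)
and the case geometry (12-deg radius, 3-deg bar). Scan-timing bookkeeping
maps a 204-s acquisition at TR 1.5 s to 136 volumes, 128 analyzed after the
12-s prescan. Scans cut short at 198 s miss the final 6 s of the cycle;
`scan_timing()` reports this as 4 missing 1.5-s frames and
`truncate_for_short_scan()` shortens the prediction to match. (The published
description calls the missing portion "two frames"; at the stated 1.5-s step
the arithmetic gives four, and the package follows the arithmetic.)

## The synthetic cortex

The generator lays V1 out as a planar retinotopic strip: cortical
magnification $u = 17\,\log(1 + e/0.75)$ mm along eccentricity and 12 mm/rad
along polar angle, covering one hemifield only — the synthetic analogue of a
single remaining hemisphere. Target areas (by default V2, V3, V3A, hV4,
LO1, LO2) are separate planar patches with jittered retinotopies. Ground
truth follows a linear size–eccentricity law
$\sigma = \text{intercept} + \text{slope}\cdot e$ (defaults 0.5 deg +
0.15 deg/deg, scaled up 1.5–3× along the hierarchy); each target vertex's
CF centre is the V1 vertex with the nearest pRF centre, with a per-area true
CF size (default 3 mm, within the few-mm range typical of V1-referred CFs).

Active runs are the pRF forward prediction plus additive AR(1) Gaussian
noise (default lag-one autocorrelation 0.4, SD expressed as a fraction of
the mean noiseless signal SD; the headline recovery analyses use 0.2).
Resting runs draw V1 latents that are spatially correlated over geodesic
distance (Gaussian kernel, default 5 mm), temporally low-pass filtered and
z-scored per vertex; each target's noiseless series is then *exactly* the CF
forward model applied to the observed V1 series, so noiseless CF recovery is
exact on the fitting grid by construction — a deliberate property that turns
CF fitting into a sharp round-trip test. Per-vertex z-scoring (rather than
mean-scaling) is the normalisation adopted for concatenated resting runs.

What the generator does *not* emulate: folded cortical anatomy,
physiological (cardiac/respiratory) noise, session drift, voxel-to-surface
interpolation error, or retinotopic map distortions. Passing recovery tests
therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to every nuisance present in real data.

## Fitting: numerical choices

- **Grid-then-refine.** pRF fitting first scores a grid (default 25 × 25
  centres over the field, 12 log-spaced sizes from 0.25 deg to the field
  radius), then refines the winner by Nelder–Mead on $(x_0, y_0, \log\sigma)$
  with parameters clamped to bounds; the refined fit is never allowed to
  score below the grid winner. Ties break toward smaller $\sigma$, then
  lexicographic $(x_0, y_0)$ — implemented by candidate ordering, so the
  first maximum wins.
- **CF grid.** Candidate sizes default to
  $\{0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20, 24, 30\}$ mm, spanning
  sub-millimetre to far beyond the typical median so that pathologically
  enlarged resting-state CFs (>9 mm) sit well inside the grid. Ties break
  toward smaller $\sigma$ then lower vertex id.
- **Aperture grid.** Movies default to 101 × 101 pixels over ±field radius.
  At this resolution the *Gaussian integration* error of the drive is below
  1% of the peak drive for $\sigma \ge 0.25$ deg (validated against a
  10 × 10 subpixel oracle in the test suite). Note that a binary aperture
  additionally quantises the bar width itself (a 2.75-deg bar is ~13.5
  pixels), which perturbs per-frame drives by a few percent of peak at any
  $\sigma$; this is a property of binary masks, affects simulation and
  fitting identically, and is invisible to VE-based fitting, which is
  scale-free per frame pattern.
- **Degenerate inputs.** Flat (zero-variance) series are flagged and scored
  VE = 0 rather than erroring; anticorrelated pRF predictions score 0 under
  the nonnegative-amplitude rule; blank frames produce zero drive exactly.
- **HRF.** The canonical two-gamma (peak 5.4 s, undershoot 10.8 s,
  dispersions 0.9 s, ratio 0.35, 32-s support), peak-normalised. The
  original analysis toolchain's HRF is not published; since simulation and
  fitting share the kernel, recovery results are insensitive to this choice,
  and every kernel parameter is configurable.

## The statistics layer

Estimates are thresholded at VE ≥ 0.20 (inclusive) and eccentricity
≤ 10.2 deg (values above the cap excluded), then grouped into early
(V1–V3) and late (V3A, hV4, LO1, LO2) areas. Per 1-deg eccentricity bin the
median size is computed with a 1000-draw percentile-bootstrap 95% CI.
Size–eccentricity trends are ordinary least squares on the binned medians
(unweighted; an L1/median-regression mode is available since published
figure captions describe quantile fits while the methods text says linear
fits — both are reported where it matters). Two-group slope differences use
the group × eccentricity interaction F-test; $\Delta\beta$ equals the
difference of the single-series slopes exactly. Patient-minus-control
median differences use a one-sample t-test at Bonferroni-corrected
α = 0.0125 (a four-comparison family). Paired viewing-condition tests mask
to units passing VE ≥ 0.20 in both conditions before testing; their
p-values are uncorrected for spatial autocorrelation and upsampling, a
caveat inherited from the underlying method and recorded in output
metadata. Relative frequency distributions use 0.5-unit bins aligned at 0
and normalise to sum 1; group averages carry t-based CIs of the per-bin
mean.

Model comparison sweeps the VE threshold from 0.20 to 0.99 (80 evenly
spaced thresholds by default — AUC is insensitive beyond the distinct-value
count) and plots HIT rate (test distribution above threshold) against FA
rate (baseline above threshold), anchored at (0,0) and (1,1); the
trapezoidal AUC is 0.5 exactly for identical distributions, and a 2000-draw
bootstrap of both distributions gives the 95% CI. The bilateral model is
the test distribution and the unilateral the baseline; by Occam's razor the
simpler unilateral model is adopted unless the AUC CI lies entirely above
0.5.

## Problem sizes used in the shipped analyses

The package's own validation analyses use: 210 V1 vertices for noisy pRF
recovery (noise 0.2 × signal SD; expected median eccentricity error
< 0.5 deg, median size error < 25%); a 64-vertex V1 with two 16-vertex
target areas for CF round-trips; and 64 V1 vertices at a 61-px aperture
grid for the three-model comparison. These sizes were chosen as the
smallest that give stable medians and clearly separated AUC decisions; all
generators and fitters scale to larger meshes with the same interfaces.

## Known limitations

- Planar synthetic meshes only; no folded-anatomy geodesics.
- No compressive spatial summation or centre–surround pRF variants, no
  per-vertex HRF estimation.
- CF fitting assumes the source ROI submesh is connected and reports the
  unreachable vertices otherwise.
- Inference on CF differences carries no spatial-autocorrelation
  correction, matching the method it reimplements.
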