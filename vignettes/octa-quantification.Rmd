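---
title: "Quantifying capillary dropout on OCTA angiograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying capillary dropout on OCTA angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement model

Optical coherence tomography angiography (OCTA) renders retinal blood flow
as en face intensity slabs. `octaquant` works on the standard 3 × 3 mm
macular protocol: a 245 × 245 pixel grid, so one pixel spans 3/245 mm, and
three depth slabs — superficial capillary plexus (SCP), deep capillary
plexus (DCP) and full retina (FR). The FR slab matters because projection
artifacts can mask true signal loss in the DCP; measuring the full retina
captures SCP and DCP change together.

Two densities are computed from each slab:

* **Perfusion density (PD)** — a thresholding algorithm converts the slab to
  a binary image (1 = perfused, 0 = background); PD is the mean of that
  binary image inside the region of interest, i.e. the area fraction
  occupied by perfused vessels.
* **Vessel density (VD)** — the binary slab is thinned to a skeleton one
  pixel wide; VD is the mean of the skeleton inside the region of interest
  divided by the pixel spacing, giving total vessel *length* per unit area
  in mm⁻¹. Each skeleton pixel contributes one pixel-spacing of length
  regardless of orientation, so diagonal runs are slightly underweighted:
  this is deliberately a first-order length estimate, kept exactly as
  defined rather than adding a √2 diagonal correction, because the
  downstream thresholds are all calibrated on the same estimator. The
  attainable ceiling is 1/pixel-spacing ≈ 81.7 mm⁻¹.

The foveal avascular zone (FAZ) is characterized by its area A, perimeter P
and circularity 4πA/P². Circularity is 1 for a perfect circle and falls as
the zone becomes irregular — an early marker of capillary loss at the
foveal margin.

## Numerical choices

**Thresholding.** The device's proprietary threshold is unpublished, so the
default is a global Otsu threshold, with `fixed` and `local_mean`
alternatives selectable. A constant image has no valid adaptive threshold;
it yields an all-background slab plus a warning rather than an error, so
batch runs continue. Absolute agreement with any vendor's numbers is out of
reach by construction — only the defining formulas are reproduced — which
is why validation runs against synthetic ground truth instead.

**Skeletonization.** Guo–Hall two-subiteration thinning, which preserves
topology and erodes free line ends less than the Zhang–Suen scheme (a
245-px straight bar keeps ≥ 243 skeleton pixels). Dense capillary meshes
leave occasional 2 × 2 junction blocks that parallel thinning cannot
reduce; these are removed by sequential 8-simple-point deletions. Two
corner cases get special handling: a junction pinched between two adjacent
one-pixel mesh holes admits no hole-preserving deletion, so a deletion that
preserves foreground connectivity but may merge a spurious one-pixel hole
with the background is allowed; and an X-crossing of two diagonal traces
("pinwheel" block) is rewritten locally, re-attaching the two arms that a
plain deletion would orphan. The guaranteed contract is: 8-connected
component count unchanged, no 2 × 2 block fully foreground, skeleton within
the 1-pixel dilation of its source.

**FAZ detection and perimeter.** The FAZ is the 4-connected background
component containing the image center, after closing the vessel foreground
with a 2-px disc so the avascular zone does not leak through
inter-capillary gaps; if the center pixel is perfused, the nearest
background pixel in a central 21 × 21 px window seeds the search. The
perimeter is a sub-pixel contour: the mask is smoothed with a σ = 1 px
Gaussian and traced by marching squares at the 0.5 level. Counting boundary
pixels instead would inflate P by the staircase factor and push disk
circularity down to ~0.89; with the smoothed contour, digitized disks
measure ≈ 0.99 and squares ≈ 0.81 against the analytic π/4 ≈ 0.785.
Discretization can push circularity above 1 by at most ε = 0.02, which is
the documented tolerance on the ≤ 1 invariant.

**Rounding.** Table formatting rounds half away from zero
(`round_half_up`), matching how clinical tables are typeset, not the IEEE
half-to-even rule.

## Disease-pathway classification

Three pathways are classified per eye against a healthy-control reference
(per-metric mean and SD; the shipped table is pooled across sexes because
the source control summary is not sex-stratified — callers with normative
sex-specific data can supply their own):

* **Macular edema** from central retinal thickness, with the DRCR.net
  sex-specific cutpoints: clinical at ≥ 290 µm (women) / ≥ 305 µm (men),
  subclinical from 260 µm / 275 µm up to those bounds. Lower bounds closed,
  upper bounds open, so categories never overlap and rising CRT never
  softens the call.
* **Neurodegeneration** when RNFL or GCL-IPL thickness falls strictly below
  the control mean minus k SD (either layer suffices).
* **Capillary dropout** when any plexus VD falls strictly below the control
  mean minus k SD.

k defaults to 2 — the conventional normative-database bound; the source
study states only "decreases", so k is exposed in the API and the 3-SD
multiplier is reserved for the progression rule, where it is stated
explicitly: a 10% VD decrease is "relevant" because it equals 3 SDs of the
healthy reference (100 · 3 · 0.7 / 21.1 = 9.95% ≈ 10%). Progression flags
use strict "more than": a decrease of exactly 10.0% is not flagged.
SD-threshold comparisons carry a 10⁻⁹ relative epsilon so a value exactly
at a printed threshold (e.g. 19.7 against 21.1 − 2 × 0.7) is not flagged
merely because of binary floating-point representation.

**Quality filter.** An eye enters longitudinal analysis only if all three
annual visits exist with device signal strength ≥ 7 and no motion-artifact
flag. Signal strength is consumed as device metadata, never recomputed from
pixels.

## The synthetic generators

No patient-level data are available, so both generators exist as
first-class, tested code.

**Angiograms** are built in continuous millimetre coordinates: a handful of
larger vessels random-walk inward from the scan border with one generation
of branching; a fine capillary mesh of short random segments is added until
the rasterized mask reaches the requested fill fraction; an elliptical
avascular zone of requested area and eccentricity is carved at center and
ringed by a perifoveal capillary arcade (which also seals the zone for
detection); the clean mask, FAZ mask and skeleton-based VD are stored as
ground truth; finally multiplicative log-normal speckle is applied, scaled
by `noise_sd` and amplified as signal strength falls below 10. Because the
network lives in physical coordinates it can be rasterized at any grid
size; VD measured at 245 px and 490 px agrees within a few percent. What
this generator does *not* emulate: real OCT speckle statistics, flow
projection artifacts, vessel caliber distributions, or eye-motion
artifacts. Passing tests therefore demonstrate that the measurement chain
recovers known geometry under plausible noise — not device equivalence.

**Cohorts** emulate the study skeleton: 84 control eyes and three diabetic
severity groups (DRSS 10–20 / 35 / 43–47) with analyzed sizes 18/17/9,
inflated to 62 enrolled diabetic eyes by largest-remainder scaling. The
three vessel densities are drawn jointly from a trivariate normal whose
correlation matrix carries the inter-plexus targets (SCP–DCP 0.77, SCP–FR
0.96, DCP–FR 0.84); every longitudinal metric follows its per-group
per-visit mean/SD trajectory, with visit-to-visit dependence modelled as an
AR(1) on the standardized deviation (persistence ρ = 0.8 by default — not
reported by any source, chosen as a realistic within-eye persistence and
exercised at 0.5/0.95 in sensitivity checks) so each visit's marginal
distribution is exact. Scan-quality failure is simulated per diabetic visit
independently with probability p solved from (1 − p)³ = 44/62, the simplest
mechanism reproducing the observed retention; controls, which serve only as
a cross-sectional reference, always pass. CRT means are shifted ± 7.5 µm by
sex (men thicker), consistent with the 15 µm separation of the sex-specific
edema cutpoints, while preserving the pooled mean. RNFL values (~6–7 µm in
the source tables) are treated as an opaque "thinning" metric and simulated
from the printed moments without anatomical interpretation.

One quirk inherited from the source tables: the ETDRS 43–47 full-retina
thickness differs between the baseline summary (267.0 µm) and the visit-1
longitudinal row (260.7 µm); the trajectories use the visit-wise values.

## The statistical battery

Group summaries report mean, SD, t-based 95% CI (level assumed, as the
source lists "confidence interval" without one) and a normalized mean
difference from control adjusted by sex. The adjustment formula is not
published; here it is the sex-composition-weighted average of the per-sex
standardized differences (group mean − control mean)/control SD — a
documented choice.

The tests are implemented from their formulas and each is cross-checked in
the test suite against an independent route (base R or brute-force
enumeration):

* Mann-Whitney U: exact by enumerating all labelings when the combined
  sample is ≤ 20 with no ties, else tie-corrected normal approximation
  without continuity correction.
* Wilcoxon signed-rank: zeros dropped (Pratt variant available); exact null
  by convolution for ≤ 25 untied differences, exact sign-pattern
  enumeration up to n = 15 with ties, else tie-corrected normal
  approximation. The switchover points were chosen for desk-scale
  tractability and the exact/approximate paths are compared near the
  boundary.
* One-way ANOVA, Pearson χ² (no continuity correction), Pearson correlation
  with t-based significance.
* MANCOVA: outcomes and the group design are residualized on the covariate
  design (equivalent to the Type II test of the group term in the additive
  model — there are no interactions and the design is near-balanced);
  Wilks' λ = det(E)/det(E + H); Rao's F approximation for the p value. With
  one outcome this collapses exactly to the one-way F through
  λ = 1/(1 + F·df_h/df_e), which the suite asserts to 10 significant
  digits, and the covariate-adjusted case matches `car::Manova` SSCP
  matrices to the same precision.

No multiple-testing correction is applied, no mixed-effects models are fit,
and missing visits are not imputed (eyes failing quality are excluded), by
design.

## Problem sizes and determinism

Everything is deterministic given a seed: identical seeds give bit-identical
images, cohorts and analysis JSON. The test suite exercises the correlation
recovery at 200 replicates of n = 44, calibration recovery at 10× group
sizes, and type-I error at 1000 null-cohort replicates; synthetic angiograms
are validated at 245 px (the native grid) with selected cases at 490 px for
resolution consistency and 145–171 px where coarser grids suffice. One
caveat learned the hard way: at grids coarser than ~200 px the 1-px
capillary mesh merges and skeleton VD saturates near 19 mm⁻¹, so
image-calibration targets above that need the native resolution.

## Known limitations

* Absolute VD/PD values depend on the unpublished vendor threshold and
  point-spread function; only the defining formulas and relative behavior
  are reproducible.
* The skeleton length estimate underweights diagonals (no √2 correction),
  as defined.
* The generator's vessel geometry is statistical, not hemodynamic; FAZ
  shapes are ellipses.
* The pooled (sex-unstratified) control reference makes the "sex-adjusted"
  normalized difference a formal adjustment only, until sex-specific
  normative values are supplied.
* MANCOVA SSCP type and covariate coding in the source software are
  unknown; the residualization route is one defensible convention.
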