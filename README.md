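# octaquant

Quantification of en face OCTA angiograms and longitudinal analysis of
early diabetic retinopathy, in R.

In the first years of nonproliferative diabetic retinopathy, three disease
pathways run at different speeds in different eyes: **capillary dropout**
(ischemia, visible as falling vessel density on OCT angiography), **macular
edema** (retinal thickening) and **neurodegeneration** (thinning of the
inner retinal layers). `octaquant` implements the full measurement and
analysis chain used to track them over repeated annual visits, for
researchers working with 3 × 3 mm macular OCTA protocols — plus synthetic
angiogram and cohort generators with ground truth, so every stage is
testable without patient data.

## The metrics

On a 245 × 245 px en face slab (3/245 mm per pixel), for each of the
superficial capillary plexus (SCP), deep capillary plexus (DCP) and full
retina (FR):

- **Perfusion density** `PD = mean(binary slab within ROI)` — area fraction
  of perfused vasculature (dimensionless).
- **Vessel density** `VD = mean(skeletonized slab within ROI) / pixel
  spacing` — vessel length per unit area (mm⁻¹), from a 1-px-wide
  topology-preserving skeleton. A first-order length estimate by
  definition.
- **FAZ metrics** (SCP): area A, sub-pixel contour perimeter P, and
  circularity `4πA/P²` of the foveal avascular zone.

Eyes are classified against a healthy-control reference (mean ± SD per
metric): capillary dropout and neurodegeneration flags at k = 2 SD below
the sex-matched control mean, sex-specific edema cutpoints (clinical
≥ 290 µm women / ≥ 305 µm men), and a longitudinal progression flag for VD
decreases of **more than 10%** — a threshold chosen because it equals a
3-SD decrease of the healthy VD reference (21.1 ± 0.7 mm⁻¹:
100·3·0.7/21.1 = 9.95% ≈ 10%). A strict quality rule (signal strength ≥ 7,
no artifacts, all three visits) gates the longitudinal analysis. The
statistical layer provides exact small-sample Mann-Whitney and Wilcoxon
signed-rank tests, one-way ANOVA, χ², Pearson correlation, sex-adjusted
normalized differences, and a Wilks'-λ MANCOVA of the VD triplet adjusted
for age, sex, HbA1c, visual acuity and diabetes duration.

## Worked example

```r
library(octaquant)

# a synthetic SCP angiogram with ground truth
gen  <- generate_angiogram(angiogram_params(rng_seed = 1), plexus = "SCP")
slab <- binarize_angiogram(gen$image, "otsu")
sk   <- skeletonize_slab(slab)

perfusion_density(slab)        # 0.3296626
vessel_density(sk)             # 15.87211  (ground truth: 15.86803 mm^-1)
fz <- detect_faz(slab)
faz_metrics(fz, slab$pixel_spacing_mm)
# $area_mm2 0.2449979   $circularity 0.9765557

# a synthetic 2-year cohort: 84 controls + 62 diabetic eyes in three
# DRSS severity groups, three annual visits
co  <- generate_cohort(cohort_config(rng_seed = 1))
res <- octa_analyze(co)

res$exclusion
# 62 enrolled, 24 excluded (39%), 38 analyzed by the three-visit quality rule

res$progression[res$progression$group == "10-20", c("plexus", "formatted")]
#   plexus    formatted
#      SCP  43.8 (7/16)     <- % of eyes with a >10% VD decrease over 2 years
#      DCP 81.3 (13/16)        (count/total), deep plexus progressing fastest
#       FR  25.0 (4/16)

res$mancova$wilks_lambda       # 0.7884688: VD triplet still differs between
res$mancova$p_value            # 0.3314121  severity groups after covariate
                               #            adjustment (this seed: ns)
```

`vessel_density` here recovers the generator's ground-truth VD to 0.03%,
and the detected FAZ area (0.245 mm²) sits within 3% of the carved 0.24 mm²
ellipse. The progression table reads like a clinical study table: each cell
is "percent (flagged/total)" for eyes whose vessel density fell by more
than 10% between baseline and year 2.

A thin command-line wrapper ships in `inst/cli/octa_pipeline.R`
(`simulate` / `quantify` / `analyze` subcommands).

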