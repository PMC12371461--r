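# myelinquant

Label-free quantification of gray-matter myelin degradation in ex vivo
brain tissue.

## The problem

Alzheimer's disease (AD) and chronic traumatic encephalopathy (CTE) are
tauopathies in which cortical myelin is thought to degrade, but gray-matter
myelin changes are hard to measure with standard imaging. Two label-free
optical modalities make them quantifiable at autopsy: **PS-OCT**
(polarization-sensitive optical coherence tomography), whose depth-resolved
retardance slope is a bulk measure of white-matter myelin content, and
**birefringence microscopy (BRM)**, which resolves individual myelinated
fibers — two parallel bright lines when healthy — and their structural
defects: swellings, delamination/blebbing, and detached lipid vesicles
visible in only 1–2 z-planes.

`myelinquant` implements the full analysis chain for neuropathology groups
working with such data:

1. **Retardance estimation** — per-voxel retardance
   φ(z) = atan2(A₁, A₂) from the two polarization channels; per-A-scan
   slope (deg/µm) by least squares along depth; feathered stitching of
   tiles acquired at 15% overlap; ROI averaging.
2. **Blinded sampling** — polygon ROIs rasterized (even-odd rule), cropped
   into 600 × 600-px sub-images (≈195 µm at 0.325 µm/px) on a randomized
   grid, ~1/3 selected and renamed with opaque tokens so annotation is
   blind to subject and group.
3. **Defect consensus** — three annotators' boxes merged when IoU ≥ 20%
   and focal planes differ by ≤ 1; defects seen by ≥ 2 annotators count;
   class disagreements become "mixed"; counts → defects/mm².
4. **Chromogen quantification** — DAB-positive percent area of stained
   ROIs by Beer–Lambert optical density and H-DAB stain unmixing.
5. **Group statistics** — linear mixed-effects models
   `density ~ group + PMI (+ age) + (1 | subject)` with Satterthwaite
   tests and Bonferroni pairwise contrasts; Spearman correlations;
   PMI-controlled standardized-β regressions. Comparing the PMI-only and
   PMI+age covariate models exposes confounding by age — in the reference
   cohort, controls average 64.0 years against 80.3 for the disease groups.
6. **Synthetic data** — generators for every input (BRM z-stacks, PS-OCT
   volumes, annotator behaviour, stained sections, age-confounded cohorts)
   with known ground truth, so each stage has an exact or statistical
   round-trip test.

## Worked example

Simulate three annotators over three true defects, merge them, and measure
density; then demonstrate the age-confounding reversal on the reference
cohort's demographics:

```r
library(myelinquant)

truth <- data.frame(x = c(40, 180, 320), y = c(60, 150, 90), w = 22, h = 22,
                    z = c(4L, 9L, 6L),
                    class = c("swelling", "delamination_blebbing", "vesicle"))
model <- annotator_model(sensitivity = 0.9, jitter_sd = 2,
                         false_positive_rate = 0.3)
ann <- simulate_annotations(truth, model, n_annotators = 3, seed = 42)
out <- consensus_pipeline(ann, area_mm2 = 0.038025)
out$defects
#>           x         y  w  h z vote_count       consensus_class  members
#> 1  42.83164  59.76537 22 22 4          2              swelling    A2,A3
#> 2 179.59870 152.51954 22 22 9          2 delamination_blebbing    A2,A3
#> 3 320.79537  92.81982 22 22 6          3               vesicle A1,A2,A3
out$record$density
#> [1] 78.89546
```

All three defects reach consensus (one annotator missed two of them; the
false positive stayed a singleton and was discarded), giving
3 / 0.038025 mm² ≈ 78.9 defects/mm².

```r
tab <- generate_cohort(cohort_spec(age_effect = 1.2),
                       demographics = study_demographics(), seed = 42)
fit_lme(tab, "pmi_only")$fixed[2, c("estimate", "p")]
#>   estimate      p
#> 2     26.5  0.025
fit_lme(tab, "pmi_age")$fixed[2, c("estimate", "p")]
#>   estimate      p
#> 2      4.0  0.767
```

This cohort was generated with **zero** group effects and a pure age effect
of 1.2 defects/mm² per year on the reference age structure. The PMI-only
model reports a "significant" CTE excess of 26.5 defects/mm² (p = 0.025);
adding age as a covariate collapses it to 4.0 (p = 0.767) — the apparent
disease effect was the age gap between groups.

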