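---
title: "Quantifying gray-matter myelin degradation from label-free imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gray-matter myelin degradation from label-free imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinquant)
```

## The problem

Alzheimer's disease (AD) and chronic traumatic encephalopathy (CTE) are
tauopathies in which gray-matter myelin is thought to degrade, but myelin
changes are hard to assess with standard imaging. Two label-free optical
modalities make them measurable in ex vivo tissue blocks:

* **PS-OCT** (polarization-sensitive optical coherence tomography) measures
  bulk tissue *retardance* — the phase delay accumulated between orthogonal
  polarization components as light traverses the ordered lipid layers of
  myelin. The steeper the retardance-versus-depth slope of an A-scan, the
  more (and more coherently oriented) myelin the beam traversed.
* **BRM** (birefringence microscopy) resolves individual myelinated fibers
  in 30-µm sections: a healthy sheath appears as two parallel bright lines,
  and structural defects — swellings, delamination/blebbing, detached lipid
  vesicles — are directly visible and countable.

`myelinquant` implements the full quantification chain for both modalities,
plus chromogen (DAB) percent-area measurement on stained sections and the
mixed-effects group statistics that tie everything together. Because the
underlying human-tissue images are not publicly available, the package pairs
every pipeline stage with a synthetic generator that produces inputs with
known ground truth; every claim the test suite makes is a round trip against
that truth or against an independent oracle (closed form, exhaustive search,
printed reference table, Monte Carlo).

## Retardance estimation

For a two-channel polarization volume, the per-voxel retardance is

$$\varphi(z) = \arctan\!\frac{A_1(z)}{A_2(z)},$$

the four-quadrant arctangent of the two amplitude channels. This ratio form
makes the angle invariant to any common positive scaling of both channels
(illumination, reflectivity), which is the property that makes "relative"
retardance comparable across samples. Angles are reported in degrees —
conventional for PS-OCT displays — and the slope of a linear fit of
$\varphi$ against physical depth, in deg/µm, is the summary measure per
A-scan ([`fit_slope()`], [`retardance_map()`]).

Numerical choices worth knowing:

* **No phase unwrapping.** Noiseless angles lie in [0°, 90°] and all
  supported (and synthetic) regimes keep the total accumulated retardance
  below the 90° wrap; a linear fit presupposes the unwrapped regime.
* **Signed angles under noise.** Near $\varphi = 0$, channel noise can push
  the computed angle slightly negative. We keep those values rather than
  folding or clamping them: folding ($|{\cdot}|$) would bias shallow-depth
  angles upward and hence bias the fitted slope. Only the *fitted slope* is
  clamped at zero (retardance cannot decrease with depth in this model).
  The package verifies that slope recovery is unbiased within 3 SE over 500
  noisy volumes.
* **`skip_top = 3` voxels** are excluded by default to avoid the surface
  specular artifact; the fit window then extends over the rest of the
  A-scan (150 µm at the acquisition geometry this mirrors). Fewer than 3
  valid points yields `NA` rather than a fit.
* Voxels where **both channels are exactly zero** carry no polarization
  information and are flagged `NA` and excluded from fitting.

Tiles are stitched ([`stitch_tiles()`]) on a grid with 15% nominal overlap.
Overlaps are blended with a separable linear feather ramp and renormalized;
this conserves constants exactly, leaves single-coverage pixels untouched,
and reproduces the expected mosaic geometry (ten 3-mm tiles at 15% overlap
span 25.95 mm). The blend mode is the package's choice — any normalized
positive weighting has the conservation property; feathering additionally
avoids visible seams in the presence of tile-to-tile offsets.

ROI means ([`roi_mean()`]) average slope over a binary mask. Gray-matter
retardance has poor signal-to-noise (far fewer myelinated axons than white
matter), so `roi_mean()` exposes `min_r_squared` to optionally exclude
low-quality fits; exclusion is a reporting decision, not a change to the
computation, and the default keeps all pixels.

## Blinded grid sampling

Annotation ROIs are drawn as polygons and rasterized with the even-odd rule
at pixel centers ([`polygon_to_mask()`]) — the pixel at row $r$, column $c$
is centered at $(c-0.5, r-0.5)$, so an axis-aligned $n \times n$ square
covers exactly $n^2$ pixels and mask areas agree with the shoelace formula
to within 1% for any polygon of at least 100 px².

[`grid_crops()`] tiles the mask's bounding box with 600-px cells
(≈195 µm at the default 0.325 µm/px) at a seed-randomized global offset and
keeps cells at least half inside the mask (`min_inside_fraction = 0.5`; how
border cells were handled in manual workflows is rarely stated, and one half
is the neutral choice). The offset is randomized **per ROI**: each region
gets an independent grid phase, which removes any systematic alignment
between grid and anatomy.

[`select_blinded()`] draws `round(fraction * N)` crops (default one third,
rounding half-up so "approximately one third" is exact and reproducible),
assigns each a 12-hex-digit token, shuffles the output, and writes the
token-to-source mapping only to a sealed key table. The sub-image records
themselves carry no subject, group or slice metadata — unblinding requires
the key file. Tokens come from the seeded RNG, so a fixed seed reproduces
the exact selection and names; they are opaque, not cryptographic.

## Defect consensus

Three annotators independently mark defects with axis-aligned boxes, a focal
z-plane, and a class (swelling, delamination/blebbing, vesicle). Two
annotations refer to the same structure when their IoU is **at least 20%**
(the threshold is inclusive — a stated minimum reads as a floor) **and**
their focal planes differ by at most **±1** (annotators legitimately focus
one plane apart, vesicles being visible in only 1–2 planes).

[`cluster_annotations()`] merges compatible annotations greedily in
descending-IoU order, with two structural constraints: a cluster may contain
at most one annotation per annotator, and *all* member pairs must be
mutually compatible (this all-pairs rule also prevents z-chaining, where
a ±1 tolerance could otherwise link planes 2 apart through a middleman).
Tie-breaks are content-based (annotator ids, then box geometry), so the
result is invariant to input order. The greedy choice is validated against
an exhaustive search over all valid partitions maximizing total
within-cluster IoU: on 1,000 random sub-image instances the two agree on
99.9% of partitions, and disagreements are boundary cases where multiple
near-equal partitions exist.

[`consensus_defects()`] keeps clusters with at least 2 votes as true
positives. The consensus class is the unanimous class when members agree;
with three members and a 2:1 split the strict majority wins; an unresolved
split — in particular any two-member disagreement — is classed **mixed**.
(The mixed category exists precisely because real defects often combine
morphologies; honoring strict majorities and reserving "mixed" for genuine
deadlock is the package's reading of that taxonomy.)

With independent annotators at sensitivity $p$ and no false positives, the
expected fraction of true defects reaching 2-of-3 consensus is
$3p^2(1-p) + p^3$ — 0.896 at $p = 0.8$ — and the simulate-then-merge round
trip reproduces it within binomial error at $p \in \{0.5, 0.8, 0.95\}$.

Counts become densities per mm² ([`defect_density()`]); a 600-px sub-image
at 0.325 µm/px covers 0.038025 mm², so e.g. 3 defects ≈ 78.9 defects/mm².
IoU is computed in 2D at the focal plane with the z tolerance handling
depth, matching how the annotations are made (single-plane boxes).

## Chromogen quantification

Stained-section images are converted to optical density by Beer–Lambert,
$OD = -\log_{10}((I + \varepsilon)/I_0)$ with $\varepsilon = 1/255$ guarding
zeros, and unmixed against the standard H-DAB reference vectors (DAB
≈ (0.268, 0.570, 0.776), hematoxylin ≈ (0.650, 0.704, 0.286), unit-
normalized) by least squares ([`dab_fraction()`]). Pixels whose DAB
concentration reaches `dab_threshold` (default 0.3 OD units — comfortably
above hematoxylin-only background and below typical chromogen density) are
positive, and the output is the percentage of ROI pixels positive.

Unmixing was chosen over interactive RGB thresholding because it is
reproducible and device-independent; an `rgb_threshold` mode is retained for
fidelity to threshold-based workflows. Neuromelanin is not modelled (its
contribution is negligible in the prefrontal ROIs this mirrors). The
generator/estimator round trip is exact to better than 1 percentage point at
every fraction from 0 to 1; with `white_point = "auto"` (99th-percentile
white estimation) the output is invariant to uniform illumination scaling.

## Group statistics

The measurement table has one row per repeated measurement (sub-image
density, or per-slice mean retardance) and constant subject-level
covariates. [`fit_lme()`] fits

$$y_{ij} = \beta_0 + \beta_{\mathrm{CTE}} + \beta_{\mathrm{AD}} +
\beta_{\mathrm{PMI}}\,\mathrm{PMI}_i \,[+\, \beta_{\mathrm{age}}\,\mathrm{age}_i]
+ b_i + \varepsilon_{ij}, \qquad b_i \sim N(0, \sigma_b^2)$$

by REML with NC as the reference level, Satterthwaite degrees of freedom
for fixed-effect tests (the default behavior class of the commercial
packages this kind of analysis is usually run in), a Type III F test for
the overall group effect, and Bonferroni correction over the $m = 3$
pairwise group contrasts. Densities are analyzed untransformed. A singular
fit (zero subject variance) falls back to the pooled least-squares fixed
effects with a warning.

The central methodological point is **confounding by age**: in the
reference cohort the controls average 64.0 years and the pooled disease
groups 80.3. If defect density rises with age at rate $\delta$ per year and
groups differ in mean age by $\Delta$, the naive group contrast is biased by
$\delta \Delta$ even with *no* disease effect. The package demonstrates the
reversal constructively: cohorts generated with a pure age effect and zero
group effects show a spurious CTE contrast under the PMI-only model that
shrinks by an order of magnitude when age enters the model. The same
comparison run on two covariate sets (`pmi_only` vs `pmi_age`) is therefore
the package's canonical analysis pattern.

Supporting analyses: [`spearman_cor()`] (rank correlation, average ranks
for ties, two-sided t-approximate p), and [`regression_controlled()`]
(all variables z-scored, OLS of defect count on chromogen percent area
controlling for PMI, standardized $\beta$s reported).

## The synthetic-data generator

The generator defines the study conditions the tests certify:

* **Cohort** ([`cohort_spec()`], [`generate_cohort()`]): 4 NC / 5 CTE /
  5 AD subjects; group age means 64 / 81.8 / 78.8 years with SDs 4.8 / 5.6 /
  8.4 (the reference demographic table's values); PMI uniform on per-group
  ranges; 16 measurements per subject (the observed mean sub-image count).
  Density model: baseline 60 defects/mm², subject-intercept SD 10, residual
  SD 20, additive group and age effects, truncation at 0. Baseline and SDs
  are the package's choice of a realistic regime — a few defects per
  0.038-mm² sub-image, between-subject spread comfortably smaller than the
  mean — such that truncation is essentially inactive (the mean sits
  2.7 pooled SDs above zero), keeping the Gaussian LME well-specified under
  the null.
* **BRM stacks** ([`render_brm_stack()`]): fibers as two parallel bright
  curves; swellings as bright bulges, delamination as locally erased sheath
  plus scattered fragments, vesicles as thin rings present in exactly 1–2
  planes. Rendering is stylized geometry, not optics — only the downstream
  counting statistics need to be realistic.
* **Annotators** ([`annotator_model()`]): independent Bernoulli detection,
  Gaussian box jitter, row-stochastic class confusion, Poisson false
  positives.
* **PS-OCT volumes** ([`simulate_psoct_volume()`]): the sin/cos two-channel
  forward model with linear-in-depth phase. The amplitude-to-retardance
  convention (channel 1 ∝ sin φ, channel 2 ∝ cos φ) is the standard
  two-channel model; the estimator is its exact inverse.
* **Stains** ([`render_stain_image()`]): smooth random blob masks thresholded
  to the exact requested pixel count, rendered through the same Beer–Lambert
  model the estimator inverts, with per-pixel concentration noise.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: speckle and coherence effects in OCT,
scattering and depth-dependent signal loss, fixation artifacts, stain
variability across labs, spatially correlated annotator errors (real
annotators miss *regions*, not independent coins), and non-Gaussian density
distributions. Results on real tissue additionally depend on ROI placement
and co-registration quality, which are manual steps outside this package.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible
under it. The bundled verification uses problem sizes chosen to give tight
oracles at interactive runtimes: 1,000 random consensus instances against
the exhaustive oracle, 1,000 simulated defects per sensitivity for the
closed-form yield, 500 replicate volumes for slope-recovery bias, 500
simulated cohorts for the type-I error of the overall group test (expected
rejection rate 0.05; observed rates fall in [0.03, 0.07]), and the full
0-to-1 sweep for the stain round trip. `scripts/acceptance.R` recomputes
all of these from scratch at any seed.

## Known limitations

* No phase unwrapping: tissues or depths accumulating more than 90° of
  retardance would need an unwrapping stage before `fit_slope()`.
* Greedy consensus is not guaranteed optimal; it is validated to ≥99%
  agreement with exhaustive search at realistic annotation densities, and
  disagreements are near-ties.
* The LME assumes Gaussian residuals on untransformed densities; strongly
  skewed real-world densities may warrant a transform or a count model.
* `fit_lme()` requires at least two groups and two subjects per group;
  single-subject groups are not estimable.
* Stain unmixing assumes the two-stain H-DAB model; additional absorbers
  (neuromelanin, hemosiderin) would need a third vector.
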