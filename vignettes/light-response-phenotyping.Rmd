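---
title: "Whole-plant light-response phenotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plant light-response phenotyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightphen)
```

# The problem

Understory evergreen shrubs manage light stress through pigments and
architecture: anthocyanins attenuate and scavenge under excess light,
chlorophyll content tracks light harvesting, and leaf movements change how
much silhouette a plant exposes to direct light. `lightphen` implements a
complete analysis chain for quantifying these responses in two standard
experimental settings:

* a **greenhouse experiment** — seedlings in a stratified blocked design
  (8 replicates x 3 light treatments x 3 blocks = 72 plants) under shade,
  ambient, and supplemental light, phenotyped by multispectral imaging,
  aerial projected-area photography, PPFD logging, and destructive harvest;
* a **common-garden experiment** — cuttings of mature plants from six
  geographic provenances grown in one environment, so that pigment
  differences reflect provenance rather than site, related to provenance
  climate via PCA and correlation analysis.

Because the package must be testable without access to any particular
glasshouse, every input has a seeded synthetic generator with known ground
truth. The generators are first-class, tested code: the study conditions
they encode (sample sizes, treatment means, noise levels, survival rates)
are fixed defaults, not tuning knobs.

# Pigment indices from multispectral captures

A capture is four single-channel 8-bit rasters of one plant: images under
green, red, and near-infrared illumination, plus a natural-light frame used
only for masking. Processing follows a strict order:

1. **Segmentation** (`segment_plant()`) on the natural-light frame;
2. **masked mean intensities** $i_{green}, i_{red}, i_{NIR}$ over plant
   pixels only (`masked_mean_intensity()`);
3. **indices from the means**:
   $$\mathrm{NDAI} = \frac{i_{red} - i_{green}}{i_{red} + i_{green}}, \qquad
     \mathrm{NDVI} = \frac{i_{NIR} - i_{red}}{i_{NIR} + i_{red}}.$$

The whole-plant means are computed first and the indices second. The
alternative — averaging per-pixel indices — is *not* equivalent (the mean of
ratios is not the ratio of means), and the package's tests pin the
means-first convention against a two-pixel counterexample. This convention
targets variation *across* plants; within-plant spatial statistics are out
of scope by design.

Indices are computed on raw mean pixel intensities, not calibrated
reflectance. That makes values comparable within an imaging setup (fixed
LEDs, camera, and exposure), which is the relevant comparison for a
treatment or provenance contrast; absolute comparability across devices is
not claimed.

## Segmentation algorithm

The masking procedure is parameter-free:

1. Reduce the natural frame to one channel (excess green $2G - R - B$ for
   RGB input, direct intensity for grayscale) and normalize to $[0, 1]$;
   `polarity = "dark"` inverts first for dark plants on bright backgrounds
   such as cardstock.
2. Otsu threshold.
3. **Opening by reconstruction**: a 3x3 box opening identifies seed
   regions; connected components of the *thresholded* mask intersecting a
   seed are retained in full. A plain opening would shave single-pixel
   boundary detail off every leaf outline; reconstruction removes isolated
   noise specks without eroding true outlines, which is what makes exact
   recovery of noise-free synthetic scenes possible (mask IoU = 1, indices
   equal to ground truth at machine precision).
4. Hole filling, then retention of the largest connected component.

A constant frame raises a segmentation-failure error; an image with no
surviving foreground raises a no-plant error carrying the plant id.

# Architecture and biomass traits

`change_in_projected_area()` computes
$(A_{final} - A_{initial}) / \mathrm{total\ leaf\ area}$, a dimensionless,
size-normalized change in plan-view silhouette between two timepoints.
Negative values mean the plant exposes less area to overhead light; in
slow-growing evergreens measured after the spring flush this predominantly
reflects leaf-angle adjustment, but the statistic itself is agnostic and the
interpretation is the caller's. Projected areas come from
`area_from_image()` (segmentation + pixel count / scale$^2$), with the
pixels-per-cm calibration supplied per imaging session by the user.

`derive_traits()` adds, with units:

| trait | definition | units |
|---|---|---|
| `sla` | total leaf area / dry leaf mass | cm$^2$ mg$^{-1}$ |
| `srl` | root length / dry root mass | cm mg$^{-1}$ |
| `rs` | dry root mass / (dry leaf + stem mass) | — |
| `total_biomass` | leaf + stem + root dry mass | mg |

"Aboveground" in R:S is leaf plus stem. Missing raw fields propagate to
missing derived values (never zero), and a zero denominator produces a
missing value with a warning while the plant is retained — per-trait sample
sizes therefore differ, and `trait_sample_sizes()` reports them.
`rs_allometry_check()` fits `rs ~ total_biomass * treatment` and reports
Type-II tests: non-significant biomass main effect and interaction support
treating R:S differences as treatment effects rather than developmental
artefacts.

# Light environment

`compute_daily_summaries()` splits a logger series at local midnight
(calendar-day convention) and computes per day
$$\mathrm{DLI} = \sum \mathrm{PPFD} \times \Delta t \times 10^{-6}
  \ \mathrm{mol\ m^{-2}\ d^{-1}},$$
the daily maximum PPFD, and `n_samples`. Days with missing samples are not
imputed; `n_samples` is exposed so callers can filter incomplete days.
`fold_ratio()` divides two treatment means and rounds half-up to one
decimal, matching how fold differences are conventionally printed (plain
`round()` rounds half-even).

# What the synthetic generators emulate

## Scenes (`scene_spec()`, `generate_multispectral_scene()`)

The plant is a union of elliptical "petals" around the frame centre on an
8-bit intensity scale. Ellipses keep the ground-truth mask analytic; the
default rosette draws petals whose semi-major axis exceeds their centre
offset, so every petal covers the frame centre and the union is connected
and star-shaped. The ground-truth mask is the hole-filled rasterized union:
crossing petals can leave single-pixel raster pockets that no real rosette
has, and a mask is only a useful truth if the plant region is
simply-connected. Pixels are drawn i.i.d. Normal per channel (foreground
mean vs. background mean, common `noise_sd`, clipped to [0, 255]). Default
foreground means (green 40, red 60, NIR 150) give NDAI = 0.2 and
NDVI ≈ 0.43; defaults for frame size (120 x 120) and petal count (6) are
free parameters chosen for fast, visually plausible rosettes. Not emulated:
lens distortion, uneven illumination, specular highlights, channel
misregistration — so segmentation accuracy on these scenes is an upper
bound on real-image performance; the closure tests validate the *pipeline's
internal consistency*, not field robustness.

## Light (`light_profile()`, `generate_ppfd_series()`)

A half-sine of amplitude `peak_ppfd` over `day_length` hours centred on
solar noon, zero at night, Gaussian flicker added to daylight samples and
clipped at 0 (night noise is not added: clipping it would bias DLI upward).
The analytic identity $\mathrm{DLI} = \mathrm{peak} \cdot (2/\pi) \cdot
\mathrm{day\ length}$ fixes the default peaks — 71, 144, 537 µmol m⁻² s⁻¹
at 14 h — so the three treatments' mean DLIs land on 2.27, 4.62, and
17.24 mol m⁻² d⁻¹. The model has no weather: day-to-day DLI variance is
far smaller than real logger data, and short sunflecks are absent, so
simulated *daily maxima* are much lower than the peaks a real greenhouse
logger records (where ambient maxima can rival supplemental light ones).
Analyses of daily maxima should treat the generator as structurally
optimistic.

## Seedling experiment (`experiment_design()`, `generate_seedling_experiment()`)

Each analysis trait follows the additive model
$$y = \mu_{treatment} + b_{block} + \varepsilon, \qquad
  b \sim N(0, \sigma_b^2),\ \varepsilon \sim N(0, \sigma_e^2),$$
with the block effect shared within a block per trait. Survival is
Bernoulli per plant (defaults 22/24, 15/24, 19/24 by treatment); dead
plants carry no end-of-experiment measurements, reproducing the unequal
downstream sample sizes a real harvest produces.

Two generalizations of the basic design were needed:

* **Per-trait dispersions.** Traits live on wildly different scales, so
  `block_sd` and `residual_sd` are per-trait named vectors (scalars
  recycle). Default residual sds are back-computed from the reported group
  standard errors (e.g. SLA ≈ 0.06 cm² mg⁻¹, total biomass ≈ 3.2 mg);
  default block sd is half the residual sd, reflecting that block variance
  in this design is real but modest (most trait models retain the mixed
  form, a minority reduce).
* **Additive model on the analysis traits, raw fields back-derived.**
  The additive model applies to NDAI, NDVI, Δ projected area, SLA, SRL,
  R:S, and total biomass; component masses, leaf area, root length, and
  projected areas are then constructed per plant to be exactly consistent
  (shoot split 2:1 leaf:stem; leaf area = SLA x leaf mass; etc.), so
  `derive_traits()` on the raw columns reproduces the generated traits to
  machine precision. Generating raw fields independently instead would
  badly bias the ratio traits — with independent area and mass at realistic
  noise, $E[A/M]$ exceeds $E[A]/E[M]$ by tens of percent — and no
  calibration target would survive.

Strictly positive traits are truncated at small physical floors (e.g.
0.2 mg for total biomass, the scale of a fine balance's resolution). With
the default (real-data-derived) dispersions this truncation shifts group
means by a few percent of a standard error and leaves a point mass at the
floor; real harvest data is right-skewed instead. The generator is a
calibration tool for group means and test behaviour, not a distributional
model of biomass.

## Provenance sample (`climate_link()`, `generate_provenance_pigments()`)

One genotype per provenance, six cuttings each (four at PSG), one index
value per cutting: provenance mean = intercept + slope x climate variable,
cutting noise Gaussian. Defaults (slope −0.012 on mean annual temperature,
sd 0.03) emulate the observed pattern of higher NDAI at colder, higher
provenances. `provenance_climate()` ships the six provenances' coordinates
and climate summaries with their northern/southern assignment.

# Inference chain

## Treatment models and singular-fit reduction

`fit_treatment_model()` fits `trait ~ treatment + (1 | block)` by REML.
If the block variance is estimated at the boundary (optimizer-reported
singularity, or block variance below $10^{-8}$ x residual variance), the
model is **reduced** to `trait ~ treatment` and flagged. Reduction is the
honest response to an uninformative variance component, and in this
balanced design it is conservative for the treatment test (block variance,
if any, inflates the residual).

One behaviour worth stating plainly: with only three blocks, a *true* block
variance of zero does **not** force a zero estimate. The REML estimate is
positive whenever the between-block mean square exceeds the within mean
square, which under a true zero happens with probability
$\approx P(F_{2,69} > 1) \approx 0.37$; simulation at the default design
reproduces this (~ 34% of zero-block-variance replicates keep the mixed
form). Reduction therefore triggers on *most*, not all, such replicates —
a property of boundary variance estimation, not a defect of the reduction
rule, and the treatment p-values of reduced and non-reduced fits agree
within Monte-Carlo error in that regime (a tested property).

`treatment_anova()` runs Type-II tests: Wald chi-square for the mixed form,
F for the reduced form — so a results table mixes the two statistic kinds
exactly as blocked-design reports conventionally do. Type II is fixed and
documented; with a single fixed factor it coincides with Type I/III here,
but the convention matters for `rs_allometry_check()`.

`tukey_pairwise()` uses model-adjusted means with Tukey family-wise
adjustment. For mixed fits, denominator df use the Satterthwaite
approximation — with three blocks, a Kenward–Roger-style correction and
Satterthwaite differ negligibly while Satterthwaite is available throughout
the toolchain. The compact letter display uses the standard
insert-and-absorb construction implemented in the package.

## Survival

`survival_lr_test()` fits a logit-link binomial GLM to grouped counts and
reports the likelihood-ratio chi-square for treatment (df = groups − 1).
Because the treatment factor saturates grouped data, the statistic equals
the closed-form null deviance
$2\sum\left[y\ln\frac{y}{\hat y} + (n-y)\ln\frac{n-y}{n-\hat y}\right]$ —
an identity the tests verify on every input. The canonical three-treatment
counts give:

```{r survival}
survival_lr_test(c(22, 15, 19), c(24, 24, 24),
                 labels = c("shade", "ambient", "supplemental"))
```

The block-free model is the reported default (`survival_test()`); a
logistic mixed model with block is available behind `include_block = TRUE`,
which flags its own singularity.

## Provenance tests

`oneway_anova_tukey()` is a one-way F test across cuttings with Tukey HSD;
unequal group sizes (6 vs 4) get the Tukey–Kramer correction automatically.
Cuttings are treated as independent replicates — with one genotype per
provenance this conflates genotype and provenance, a design caveat the
analysis inherits rather than hides. The degenerate all-values-equal case
(0/0 in the F ratio) is *defined* as F = 0, p = 1: no between-group
variance is evidence of no effect, not an error. `region_means_test()`
compares the six provenance *means* across the northern/southern split
(df = 1 and 4): deliberately coarse, acknowledging n = 3 per region.

## Climate PCA and correlations

`pca_climate()` centres and scales each variable, returning
min(rows − 1, columns) components, orthonormal loadings, and variance
fractions that sum to 1; constant columns are rejected by name. On the
bundled six-variable provenance table, PC1/PC2 carry ~82%/17% of climate
variance. `correlation_matrix()` computes pairwise-complete Pearson r with
two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$ on n − 2 df, with **no**
multiplicity adjustment (per-cell significance reporting); a zero-variance
variable yields flagged missing correlations, never a silent zero. With
n = 6 provenances these correlations are descriptive: only |r| ≳ 0.81
reaches p < 0.05, and the climate variables are strongly intercorrelated,
so no causal attribution among them is possible from this design.

# Numerical conventions

* Seeded determinism: every generator is a pure function of (spec, seed)
  and restores the caller's RNG state.
* Intensities are 8-bit [0, 255]; PNG round-trips quantize to half a grey
  level.
* Fold ratios round half-up to one decimal; nothing else is rounded before
  output.
* Singular-fit tolerance: block variance < $10^{-8}$ x residual variance.
* Degenerate one-way ANOVA (no between-group variance): F = 0, p = 1.
* Errors are classed conditions (`lightphen_invalid_spec`,
  `lightphen_no_plant`, `lightphen_undefined_index`, ...) so callers can
  discriminate failure modes.

# Problem sizes in the test suite

The suite's Monte-Carlo checks use sizes chosen to bound sampling error
well below the margins being asserted while keeping a full run around two
minutes: 100 scenes for index recovery, 2000 replicates for survivor-count
calibration, 500 for group-mean calibration, 1000 null and 200 power
replicates for ANOVA calibration, and 200 replicates for variance-component
recovery. All seeds are fixed; reruns are bit-identical.

# Known limitations

* Synthetic scenes cannot certify segmentation on real images (shadows,
  soil, overlapping neighbours).
* The light model omits weather and sunflecks; daily-maximum statistics are
  structurally understated.
* Trait distributions are truncated Gaussians, not the right-skewed
  distributions real harvests produce; calibration claims concern group
  means and test operating characteristics only.
* With three blocks, block-variance estimates are very noisy; mixed-vs-
  reduced classification of any single experiment is unstable near zero
  block variance (the treatment inference is robust to it).
* The provenance analyses inherit the one-genotype-per-provenance
  confound and n = 6 for all mean-level correlations.
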