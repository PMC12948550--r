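# lightphen

Whole-plant light-response phenotyping in R: multispectral pigment indices,
plant-architecture and biomass traits, daily light integrals, and the full
statistical chain for blocked greenhouse light-treatment experiments and
provenance common gardens. Written for plant ecophysiologists who phenotype
understory shrubs (or any rosette-forming seedlings) under contrasting light
environments and want a tested, reproducible path from raw images and logger
files to treatment contrasts and climate correlations.

## What it computes

**Pigment indices.** A plant mask is segmented from a natural-light frame
(Otsu threshold + opening-by-reconstruction + hole fill + largest
component), mean pixel intensities are extracted under green, red, and
near-infrared illumination over that mask, and the two indices are computed
from the whole-plant means:

    NDAI = (i_red − i_green) / (i_red + i_green)     (anthocyanin proxy)
    NDVI = (i_NIR − i_red) / (i_NIR + i_red)         (chlorophyll proxy)

**Architecture and biomass.** Projected area from aerial photographs
(pixels / scale²), the normalized change in projected area
`(A_final − A_initial) / total leaf area`, and the derived traits SLA
(cm² mg⁻¹), SRL (cm mg⁻¹), root:shoot ratio, and total biomass (mg), with
missingness propagated so per-trait sample sizes stay honest.

**Light environment.** Daily light integral
`DLI = Σ PPFD × Δt × 10⁻⁶ mol m⁻² d⁻¹` and daily maxima from 300-s PPFD
logger series; per-treatment spot-measurement summaries; fold ratios of
treatment means.

**Inference.** Linear mixed models `trait ~ treatment + (1 | block)` with
automatic reduction to simple linear models on singular block-variance
fits; Type-II ANOVA (χ² for mixed, F for simple linear); Tukey-adjusted
pairwise contrasts with compact letter displays; a grouped binomial GLM
likelihood-ratio test for survival; one-way provenance ANOVA with
Tukey–Kramer HSD; a northern-vs-southern test on provenance means; scaled
and centered climate PCA; and a Pearson correlation matrix with per-cell
t-transform p-values.

**Synthetic data.** Seeded generators for every input — multispectral
rosette scenes with exact mask and index ground truth, diurnal PPFD traces
calibrated to treatment DLIs of 2.27 / 4.62 / 17.24 mol m⁻² d⁻¹, blocked
seedling trait tables with binomial survival (22/24, 15/24, 19/24), and
climate-linked provenance pigment samples (6 cuttings per provenance, 4 at
PSG).

## Worked example

```r
library(lightphen)

# a synthetic capture with known truth (NDAI 0.2, NDVI 0.4286), processed
# back through the imaging chain
sc <- generate_multispectral_scene(scene_spec(noise_sd = 6, seed = 42), "demo")
process_capture(sc$capture)
#>   plant_id  i_green    i_red   i_nir      ndai      ndvi
#> 1     demo 40.04755 60.20195 150.023 0.2010424 0.4272615

# five days of supplemental-light PPFD, summarized
s <- generate_ppfd_series(light_profile("supplemental", n_days = 5, seed = 42))
head(compute_daily_summaries(s), 3)
#>   day      dli max_ppfd n_samples
#> 1   0 17.13845 616.7308       288
#> 2   1 17.25060 641.0850       288
#> 3   2 17.18121 639.4703       288

# survival across the three light treatments, 24 seedlings each
survival_lr_test(c(22, 15, 19), c(24, 24, 24),
                 labels = c("shade", "ambient", "supplemental"))
#>   response   model_form statistic_kind statistic df1 df2    p_value ...
#> 1 survival glm_binomial          chisq  6.191007   2  NA 0.04525223
```

The recovered indices sit within 0.002 of the generator's truth; each
simulated day's DLI scatters tightly around the 17.24 mol m⁻² d⁻¹ target;
and the survival likelihood-ratio χ² of 6.19 on 2 df (p = 0.045) indicates
a treatment effect on seedling survival.

## Analysis workflow

The `analysis/` scripts run the two experiments end to end on simulated
inputs, writing tables under `results/`:

| script | does |
|---|---|
| `01_simulate_inputs.R` | scenes, PPFD traces, seedling table, provenance sample |
| `02_imaging_indices.R` | segmentation + indices vs. ground truth |
| `03_light_environment.R` | DLI/max summaries, spot summaries, fold ratios |
| `04_greenhouse_inference.R` | per-trait mixed models, ANOVA, Tukey letters, survival, R:S allometry |
| `05_common_garden.R` | provenance ANOVA, region test, climate PCA, correlations |

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

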