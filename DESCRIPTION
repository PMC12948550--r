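Package: lightphen
Title: Whole-Plant Light-Response Phenotyping from Multispectral Images,
    Light Logs, and Trait Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-plant responses to light environment in
    greenhouse and common-garden experiments. Provides seeded synthetic-data
    generators (multispectral rosette scenes with known pigment ground truth,
    diurnal photosynthetic photon flux density traces, blocked seedling trait
    tables with binomial survival, and provenance pigment samples linked to
    climate); plant segmentation and masked mean-intensity extraction with the
    normalized difference anthocyanin and vegetation indices (NDAI, NDVI);
    projected-area and biomass trait derivation (SLA, SRL, root:shoot, total
    biomass, normalized change in projected area); daily light integral and
    maximum summaries from logger series; and the full inference chain:
    mixed-effects treatment models with singular-fit reduction, Type-II ANOVA,
    Tukey-adjusted contrasts with compact letter displays, a binomial survival
    likelihood-ratio test, provenance one-way ANOVA with Tukey-Kramer HSD,
    northern-versus-southern region tests, scaled-and-centered climate PCA, and
    a Pearson correlation matrix with per-cell significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    car,
    emmeans,
    lme4,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
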