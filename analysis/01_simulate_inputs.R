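#!/usr/bin/env Rscript
# Simulate every input the downstream analyses need: multispectral captures
# with ground truth, per-treatment PPFD logger traces, the blocked seedling
# trait table, and the common-garden provenance pigment sample.

suppressPackageStartupMessages(library(lightphen))

seed <- 20260401L
out <- "results"
dir.create(out, showWarnings = FALSE)

# -- multispectral scenes: 12 plants at moderate sensor noise ---------------
scenes <- lapply(1:12, function(i) {
  generate_multispectral_scene(scene_spec(noise_sd = 6, seed = seed + i),
                               plant_id = sprintf("plant_%02d", i))
})
truth <- do.call(rbind, lapply(scenes, function(s) {
  data.frame(plant_id = s$capture$plant_id,
             true_ndai = s$truth$true_ndai, true_ndvi = s$truth$true_ndvi)
}))
write.csv(truth, file.path(out, "scene_ground_truth.csv"), row.names = FALSE)
# captures are not persisted; 02 regenerates them from the same seed

# -- PPFD logger traces: one sensor per treatment ---------------------------
# persist one illustrative day per treatment; 03 regenerates the full 30-day
# series from this same seed
for (tr in c("shade", "ambient", "supplemental")) {
  s <- generate_ppfd_series(light_profile(tr, n_days = 1, seed = seed))
  write_ppfd_csv(s, file.path(out, paste0("ppfd_", tr, "_day1.csv")))
}

# -- seedling trait table: 8 replicates x 3 treatments x 3 blocks -----------
traits <- generate_seedling_experiment(experiment_design(seed = seed))
write.csv(traits, file.path(out, "seedling_traits.csv"), row.names = FALSE)
cat(sprintf("seedlings: %d, survivors: %d (%s)\n", nrow(traits),
            sum(traits$survived),
            paste(tapply(traits$survived, traits$treatment, sum), collapse = "/")))

# -- provenance pigments: 6 cuttings per provenance (4 at PSG) --------------
pig <- generate_provenance_pigments(climate_link(seed = seed))
write.csv(pig, file.path(out, "provenance_ndai.csv"), row.names = FALSE)
cat("provenance cuttings:", nrow(pig), "\n")
cat("inputs written to", out, "\n")
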