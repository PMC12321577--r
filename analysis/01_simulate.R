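#!/usr/bin/env Rscript
# Simulate one complete synthetic septum field with ground truth and write
# it (image stack, atlas, truth tables, manifest) under results/simulation/.
# All downstream analysis scripts re-derive their inputs from this run.

suppressPackageStartupMessages(library(septastro))

seed <- 20250101L
out_dir <- file.path("results", "simulation")

cfg <- synth_config()                 # study conditions: defaults
sim <- simulate_septum(cfg, seed = seed, shape_yx = c(800, 800),
                       n_astro_per_region = 5)
write_simulation(sim, out_dir)

cat(sprintf("simulated %d astrocytes, %d pre / %d post puncta, %d census cells\n",
            length(sim$cells), nrow(sim$puncta$pre_um),
            nrow(sim$puncta$post_um), nrow(sim$census)))
cat("wrote", out_dir, "\n")
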