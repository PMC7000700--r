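#!/usr/bin/env Rscript
# Simulate the demonstration primary screen: three runs of the 1536-well
# FLT-FRET assay over a 1280-compound library with 256 DMSO control wells
# per plate, spiked with 17 strong and 5 marginal RyR modulators.
# Writes the long-format plate tables consumed by 02_screen_analysis.R.

suppressPackageStartupMessages(library(fretscreen))
dir.create("results", showWarnings = FALSE)

cfg <- screen_sim_config(effect_table = demo_effect_table(), seed = 1)
sim <- simulate_screen(cfg)

utils::write.csv(sim$plates, "results/plates.csv", row.names = FALSE)
utils::write.csv(sim$truth, "results/true_effects.csv", row.names = FALSE)

cat(sprintf("Simulated %d runs x 3 plates x 1536 wells (%d rows) -> results/plates.csv\n",
            cfg$n_runs, nrow(sim$plates)))
cat(sprintf("Spiked modulators: %d strong (all runs), %d marginal (2 of 3 runs)\n",
            sum(!is.na(sim$truth$effect) & sim$truth$effect != 0 &
                  is.na(sim$truth$runs_active)),
            sum(!is.na(sim$truth$runs_active))))
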