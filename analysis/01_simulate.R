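#!/usr/bin/env Rscript
# Step 1 — simulate the study's sample designs.
#
# Generates one shared replication-timing landscape (10 Mb in five
# chromosomes, 10-kb bins) and coverage tracks at 1e6 fragments per sample
# for: a quiescent population (the sperm-like query and its reference), a
# synchronized fully S-phase culture (the positive control), and three
# DNA-stain-intensity subfractions of increasing S-phase content.
# Everything is written under results/sim/ as bedGraph plus ground truth.

suppressMessages(library(repliseek))

out <- "results/sim"
seed <- 20260924L
lay <- default_layout(1e7, 5, 1e4)
timing <- simulate_timing(lay, correlation_length = 1e6, seed = seed)

main <- simulation_scenario(
  lay,
  list(population_model(0, label = "quiescent_query"),
       population_model(0, label = "reference"),
       population_model(1, "beta", 5, 5, label = "synchronized_s")),
  timing = timing, depth = 1e6, seed = seed, label = "main")
sim <- run_simulate(main, out)

pi3 <- scenario_preset("pi_fractions", layout = lay, timing = timing,
                       depth = 1e6, seed = seed + 1L)
run_simulate(pi3, file.path(out, "pi_fractions"))

# the timing landscape itself, as the reference track later steps consume
write_track(coverage_track(lay, timing$values, label = "timing"),
            file.path(out, "timing.bedGraph"))

message(sprintf("simulated %d samples + 3 PI subfractions onto %d bins; ",
                length(sim$tracks), n_bins(lay)),
        sprintf("mean copy number of synchronized sample: %.3f",
                mean(sim$fields$synchronized_s$c)))
message("outputs in ", normalizePath(out))
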