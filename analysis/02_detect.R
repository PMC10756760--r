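#!/usr/bin/env Rscript
# Step 2 — run the replication detector on the simulated samples.
#
# Reproduces the study's comparison logic on the synthetic data from step 1:
# (i) quiescent query vs. reference — expected NOT replicating (the
# sperm-vs-vegetative comparison); (ii) synchronized S-phase culture vs.
# reference — expected replicating (the S-vs-G1 control); (iii) the three
# stain-intensity subfractions vs. reference, with S-fraction estimates.
# Reports land under results/detect/<comparison>/.

suppressMessages(library(repliseek))

simdir <- "results/sim"
if (!dir.exists(simdir)) stop("run analysis/01_simulate.R first")
genome <- file.path(simdir, "genome.chrom.sizes")
timing <- file.path(simdir, "timing.bedGraph")
ref <- file.path(simdir, "reference.bedGraph")

comparisons <- c(
  quiescent = file.path(simdir, "quiescent_query.bedGraph"),
  synchronized_s = file.path(simdir, "synchronized_s.bedGraph"),
  pi_low = file.path(simdir, "pi_fractions", "pi_low.bedGraph"),
  pi_mid = file.path(simdir, "pi_fractions", "pi_mid.bedGraph"),
  pi_high = file.path(simdir, "pi_fractions", "pi_high.bedGraph")
)

rows <- lapply(names(comparisons), function(nm) {
  rep <- run_detect(query = comparisons[[nm]], reference = ref,
                    genome = genome, bin_size = 1e4, timing = timing,
                    timing_orientation = "quantile",
                    out_dir = file.path("results/detect", nm),
                    alpha = 0.05,
                    config = list(n_perm = 199, seed = 42L, n_boot = 100))
  message(sprintf(
    "%-15s decision=%-15s r=%+.3f p_timing=%.4g ac=%+.3f p_ac=%.4g p_hat=%s",
    nm, rep$decision, rep$pearson_r, rep$p_timing, rep$ac_statistic, rep$p_ac,
    if (is.null(rep$estimate)) "-" else sprintf("%.3f", rep$estimate$p_hat)))
  cbind(comparison = nm, as.data.frame(rep))
})

summary <- do.call(rbind, rows)
write.table(summary, "results/detect/summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("combined report: results/detect/summary.tsv")
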