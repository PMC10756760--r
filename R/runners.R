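#' Convert a coverage track to a timing profile
#'
#' External replication-timing references (e.g. EdU-enrichment tracks from
#' early-S cells) arrive as arbitrary-scale signals. `"early_high"` means
#' higher signal = earlier replication (EdU convention); `"late_high"` the
#' reverse; `"quantile"` means the values are already timing quantiles in
#' \[0,1\] with 0 = earliest. Rank transformation uses average ranks for
#' ties.
#'
#' @param track a `coverage_track` carrying the reference signal.
#' @param orientation one of `"quantile"`, `"early_high"`, `"late_high"`.
#' @return a `timing_profile`.
#' @export
as_timing_profile <- function(track, orientation = c("quantile", "early_high", "late_high")) {
  stopifnot(inherits(track, "coverage_track"))
  orientation <- match.arg(orientation)
  v <- track$values
  n <- length(v)
  q <- switch(orientation,
    quantile = {
      if (any(v < 0 | v > 1)) {
        stop("orientation 'quantile' requires values in [0, 1]", call. = FALSE)
      }
      v
    },
    early_high = (rank(-v, ties.method = "average") - 0.5) / n,
    late_high = (rank(v, ties.method = "average") - 0.5) / n
  )
  timing_profile(track$layout, q)
}

#' Simulate a scenario and write its tracks and ground truth to disk
#'
#' Writes one bedGraph per population, a per-population ground-truth TSV
#' (`chrom`, `start`, `end`, `timing`, `replicated_fraction`,
#' `copy_number`), the genome as chrom.sizes, and a YAML run manifest.
#' Outputs are a deterministic function of the scenario seed.
#'
#' @param scenario a `simulation_scenario` (see [scenario_preset()]), or a
#'   path to a YAML scenario config (see [read_scenario_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [simulate_scenario()] result.
#' @export
run_simulate <- function(scenario, out_dir) {
  if (is.character(scenario)) scenario <- read_scenario_config(scenario)
  stopifnot(inherits(scenario, "simulation_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_scenario(scenario)
  layout <- scenario$layout
  utils::write.table(
    layout$chromosomes, file.path(out_dir, "genome.chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (lab in names(sim$tracks)) {
    write_track(sim$tracks[[lab]], file.path(out_dir, paste0(lab, ".bedGraph")))
    truth <- data.frame(chrom = layout$bins$chrom,
                        start = format_bp(layout$bins$start),
                        end = format_bp(layout$bins$end),
                        timing = sim$timing$values,
                        replicated_fraction = sim$fields[[lab]]$r,
                        copy_number = sim$fields[[lab]]$c)
    utils::write.table(truth, file.path(out_dir, paste0("truth_", lab, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    label = scenario$label, bin_size = layout$bin_size,
    depth = scenario$depth, seed = scenario$seed,
    correlation_length = scenario$correlation_length,
    populations = lapply(scenario$populations, function(p) {
      list(label = p$label, p_s = p$p_s, progression = p$progression)
    }))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(sim)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Run the detection pipeline on track files and write its report
#'
#' Reads query and reference coverage (bedGraph on the genome's bin
#' lattice), optionally a replication-timing reference, runs
#' [detect_replication()], and writes `report.tsv` (flat one-row report),
#' `autocorrelation.tsv` (`lag_bp`, `rho`, `pairs`), `ratio.bedGraph`, and a
#' YAML manifest recording masking, normalization totals and seeds.
#' Progress and masking counts are logged via [message()].
#'
#' @param query,reference bedGraph paths, or `coverage_track`s.
#' @param genome chrom.sizes path (required when tracks are given as paths).
#' @param bin_size bin width in bp of the input tracks.
#' @param timing optional timing bedGraph path or `timing_profile`.
#' @param timing_orientation how to read the timing signal; see
#'   [as_timing_profile()].
#' @param out_dir output directory.
#' @param alpha significance level.
#' @param config extra [detect_replication()] config entries.
#' @return invisibly, the `detection_report`.
#' @export
run_detect <- function(query, reference, genome = NULL, bin_size = 1e4,
                       timing = NULL, timing_orientation = "quantile",
                       out_dir, alpha = 0.05, config = list()) {
  if (is.character(query) || is.character(reference)) {
    if (is.null(genome)) stop("genome (chrom.sizes) required with file inputs", call. = FALSE)
    layout <- read_chrom_sizes(genome, bin_size = bin_size)
    if (is.character(query)) query <- read_bedgraph(query, layout)
    if (is.character(reference)) reference <- read_bedgraph(reference, layout)
    if (is.character(timing)) {
      timing <- as_timing_profile(read_bedgraph(timing, layout), timing_orientation)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- detect_replication(query, reference, timing = timing,
                               alpha = alpha, config = config)
  message(sprintf("detect: %d/%d bins used (%d masked), normalized total %.6g",
                  report$n_bins_used, n_bins(report$ratio$layout),
                  report$ratio$n_masked, report$totals))
  message(sprintf("detect: decision = %s%s", report$decision,
                  if (isTRUE(report$degenerate)) " (degenerate ratio)" else ""))
  utils::write.table(as.data.frame(report), file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ac_curve)) {
    utils::write.table(
      data.frame(lag_bp = report$ac_curve$lags, rho = report$ac_curve$rho,
                 pairs = report$ac_curve$pair_counts),
      file.path(out_dir, "autocorrelation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_track(report$ratio, file.path(out_dir, "ratio.bedGraph"))
  yaml::write_yaml(
    list(alpha = alpha, seed = report$config$seed, n_perm = report$config$n_perm,
         lag_window = report$config$lag_window, max_lag = report$config$max_lag,
         n_masked = report$ratio$n_masked, normalized_total = report$totals,
         decision = report$decision),
    file.path(out_dir, "manifest.yaml"))
  invisible(report)
}

#' Run a power sweep and write its table and summary
#'
#' @param spec a `sweep_spec`.
#' @param out_dir output directory.
#' @param target_power power level at which to report the minimal
#'   detectable S-phase fraction.
#' @param verbose forwarded to [run_sweep()].
#' @return invisibly, the `power_table`.
#' @export
run_power <- function(spec, out_dir, target_power = 0.8, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- run_sweep(spec, verbose = verbose)
  utils::write.table(as.data.frame(tab), file.path(out_dir, "power_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- vapply(spec$depths, function(d) {
    mdf <- minimal_detectable_fraction(tab, target_power, depth = d)
    sprintf("depth %g: minimal detectable S-phase fraction at power %.2f = %s",
            d, target_power, if (is.na(mdf)) "not attained" else sprintf("%.4f", mdf))
  }, "")
  writeLines(lines, file.path(out_dir, "summary.txt"))
  message(paste(lines, collapse = "\n"))
  invisible(tab)
}
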