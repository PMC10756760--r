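#' Specify a detection-power sweep
#'
#' A grid over S-phase fractions and sequencing depths; each cell is
#' simulated `n_replicates` times (query at `p_s` vs. a non-replicating
#' reference drawn from the same timing landscape) and run through
#' [detect_replication()] and the S-fraction estimator. Replicate seeds are
#' derived from the spec seed by counter, so any cell can be re-run in
#' isolation and seeds are matched across `p_s` and depth (the same
#' replicate index reuses the same timing landscape and sampling stream).
#'
#' @param p_s S-phase fractions to sweep.
#' @param depths total fragments per sample.
#' @param genome_size,n_chrom,bin_size synthetic genome (see
#'   [default_layout()]).
#' @param n_replicates replicates per grid cell.
#' @param alpha significance level.
#' @param n_perm permutations per test.
#' @param n_boot bootstrap replicates for the estimator (0 = point estimate
#'   only).
#' @param correlation_length timing smoothness in bp.
#' @param seed master seed.
#' @return a `sweep_spec`.
#' @export
sweep_spec <- function(p_s = c(0, 0.05, 0.1, 0.2, 0.3, 0.6, 1.0),
                       depths = c(1e5, 1e6),
                       genome_size = 1e7, n_chrom = 5, bin_size = 1e4,
                       n_replicates = 50, alpha = 0.05, n_perm = 99,
                       n_boot = 0, correlation_length = 1e6, seed = 1) {
  stopifnot(all(p_s >= 0 & p_s <= 1), all(depths >= 1), n_replicates >= 1,
            alpha > 0, alpha < 1)
  structure(list(p_s = sort(p_s), depths = depths, genome_size = genome_size,
                 n_chrom = n_chrom, bin_size = bin_size,
                 n_replicates = n_replicates, alpha = alpha, n_perm = n_perm,
                 n_boot = n_boot, correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

# counter-derived 31-bit replicate seed
replicate_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(counter)) %% (2^31 - 1))
}

#' Run a detection-power sweep
#'
#' @param spec a `sweep_spec`.
#' @param verbose print one progress line per grid cell.
#' @return a `power_table` data.frame with one row per (depth, p_s) cell:
#'   per-test rejection rates (`power_timing`, `power_ac`), the combined
#'   Bonferroni decision rate (`power_combined`), and the mean and sd of the
#'   estimated S fraction. Failed replicates are recorded in the
#'   `failures` attribute and excluded from the rates.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  layout <- default_layout(spec$genome_size, spec$n_chrom, spec$bin_size)
  ref_pop <- population_model(0, "uniform", label = "reference")
  rows <- list()
  failures <- list()
  for (depth in spec$depths) {
    for (ps in spec$p_s) {
      pop <- population_model(ps, "uniform", label = sprintf("p%.2f", ps))
      res <- lapply(seq_len(spec$n_replicates), function(i) {
        sd0 <- replicate_seed(spec$seed, i)
        tryCatch({
          timing <- simulate_timing(layout, spec$correlation_length, seed = sd0)
          fq <- replicated_fraction(timing, pop)
          fr <- replicated_fraction(timing, ref_pop)
          q <- simulate_coverage(fq, depth, seed = replicate_seed(sd0, 1))
          r <- simulate_coverage(fr, depth, seed = replicate_seed(sd0, 2))
          rep <- detect_replication(q, r, timing, alpha = spec$alpha,
                                    config = list(n_perm = spec$n_perm,
                                                  n_boot = spec$n_boot,
                                                  seed = replicate_seed(sd0, 3)))
          data.frame(p_timing = rep$p_timing, p_ac = rep$p_ac,
                     rejected = rep$decision == "replicating",
                     p_hat = if (is.null(rep$estimate)) NA_real_ else rep$estimate$p_hat)
        }, error = function(e) e)
      })
      is_err <- vapply(res, inherits, TRUE, what = "error")
      if (any(is_err)) {
        failures[[length(failures) + 1L]] <- data.frame(
          p_s = ps, depth = depth, replicate = which(is_err),
          message = vapply(res[is_err], conditionMessage, ""))
      }
      df <- do.call(rbind, res[!is_err])
      rows[[length(rows) + 1L]] <- data.frame(
        p_s = ps, depth = depth, n_replicates = nrow(df),
        power_timing = mean(df$p_timing <= spec$alpha),
        power_ac = mean(df$p_ac <= spec$alpha),
        power_combined = mean(df$rejected),
        mean_p_hat = mean(df$p_hat), sd_p_hat = stats::sd(df$p_hat))
      if (verbose) {
        message(sprintf("depth %g, p_s %.2f: power %.2f", depth, ps,
                        rows[[length(rows)]]$power_combined))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- spec$alpha
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else NULL
  class(out) <- c("power_table", class(out))
  out
}

#' Smallest detectable S-phase fraction at a target power
#'
#' Returns the smallest `p_s` at which the combined detection power reaches
#' `target_power`, linearly interpolating between the bracketing grid
#' points; `NA` if the target is never reached. This quantifies the largest
#' replicating subpopulation a non-significant result can exclude.
#'
#' @param table a `power_table` (one depth, or use `depth` to select one).
#' @param target_power required power in (0, 1\].
#' @param depth depth to select when the table spans several.
#' @return interpolated `p_s`, or `NA_real_` if unattained.
#' @export
minimal_detectable_fraction <- function(table, target_power = 0.8, depth = NULL) {
  stopifnot(inherits(table, "power_table") || is.data.frame(table))
  tab <- as.data.frame(table)
  if (!is.null(depth)) tab <- tab[tab$depth == depth, ]
  if (length(unique(tab$depth)) > 1L) {
    stop("table spans several depths; pass `depth`", call. = FALSE)
  }
  tab <- tab[order(tab$p_s), ]
  hit <- which(tab$power_combined >= target_power)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(tab$p_s[1L])
  p0 <- tab$p_s[i - 1L]; p1 <- tab$p_s[i]
  w0 <- tab$power_combined[i - 1L]; w1 <- tab$power_combined[i]
  if (w1 == w0) return(p1)
  p0 + (target_power - w0) / (w1 - w0) * (p1 - p0)
}
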