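#' Correlation of a coverage ratio with replication timing
#'
#' Pearson correlation between the per-bin log2 query/reference ratio and a
#' replication-timing signal oriented so that higher = earlier-replicating
#' (internally `1 - T`, since the timing quantile `T` is 0 at the
#' earliest-replicating bins). If the query population contains replicating
#' cells, early bins carry excess copy number and the correlation is
#' positive; a non-replicating population gives correlation near zero.
#' Masked bins are excluded pairwise.
#'
#' @param ratio a `ratio_track`.
#' @param timing a `timing_profile` on the same layout.
#' @return list with `r` (Pearson correlation) and `n` (bins used).
#' @export
pearson_timing <- function(ratio, timing) {
  stopifnot(inherits(ratio, "ratio_track"), inherits(timing, "timing_profile"))
  if (!same_layout(ratio$layout, timing$layout)) {
    stop("ratio and timing are on different layouts", call. = FALSE)
  }
  ok <- !ratio$mask
  n <- sum(ok)
  if (n < 10L) stop("fewer than 10 usable bins", call. = FALSE)
  x <- ratio$values[ok]
  y <- 1 - timing$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in ratio or timing signal", call. = FALSE)
  }
  list(r = stats::cor(x, y), n = n)
}

# split a per-bin vector into per-chromosome pieces, NA at masked bins
split_by_chrom <- function(layout, values, mask = NULL) {
  v <- values
  if (!is.null(mask)) v[mask] <- NA_real_
  unname(split(v, factor(layout$bins$chrom, levels = layout$chromosomes$name)))
}

# pooled lag autocorrelation over per-chromosome vectors (NA = masked):
# per-chromosome mean-centering, then for each lag k the sum of products of
# unmasked pairs (i, i+k) pooled across chromosomes and divided by
# (pair count * genome-wide variance of the centered signal).
ac_pooled <- function(vlist, ks) {
  centered <- lapply(vlist, function(v) {
    if (all(is.na(v))) return(v)
    v - mean(v, na.rm = TRUE)
  })
  allv <- unlist(centered)
  un <- which(!is.na(allv))
  if (length(un) < 2L) stop("fewer than 2 unmasked bins", call. = FALSE)
  varg <- sum(allv[un]^2) / length(un)
  if (varg <= 0) stop("zero variance in signal", call. = FALSE)
  num <- numeric(length(ks))
  cnt <- numeric(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    for (v in centered) {
      n <- length(v)
      if (n > k) {
        pr <- v[seq_len(n - k)] * v[seq(k + 1L, n)]
        ok <- !is.na(pr)
        num[j] <- num[j] + sum(pr[ok])
        cnt[j] <- cnt[j] + sum(ok)
      }
    }
  }
  list(rho = ifelse(cnt > 0, (num / cnt) / varg, NA_real_), pair_counts = cnt)
}

#' Spatial autocorrelation of a genomic signal
#'
#' Because replication timing is spatially smooth, a population with
#' replicating cells shows positive autocorrelation of its coverage ratio
#' between nearby positions, whatever the replication order — this is the
#' reference-free detector. The signal is mean-centered per chromosome (so
#' between-chromosome level differences cannot inflate the statistic); for
#' each lag `d = k * bin_size` the products of all within-chromosome
#' unmasked bin pairs at that distance are pooled across chromosomes (sum of
#' numerators and of pair counts, divided once) and scaled by the
#' genome-wide variance of the centered signal. No pair spans a chromosome
#' boundary or a masked bin.
#'
#' @param ratio a `ratio_track`.
#' @param max_lag largest lag in base pairs (>= `bin_size`).
#' @param signal `"log2"` uses the stored log2 ratios; `"linear"` transforms
#'   them back to linear ratios (`2^value`) first.
#' @return an `ac_curve`: list with `lags` (bp), `rho`, `pair_counts`,
#'   restricted to lags with at least one pair.
#' @export
autocorrelation <- function(ratio, max_lag = 1e6, signal = c("log2", "linear")) {
  stopifnot(inherits(ratio, "ratio_track"))
  signal <- match.arg(signal)
  bs <- ratio$layout$bin_size
  if (max_lag < bs) stop("max_lag must be >= bin_size", call. = FALSE)
  ks <- seq_len(floor(max_lag / bs))
  v <- ratio$values
  if (signal == "linear") v <- 2^v
  vlist <- split_by_chrom(ratio$layout, v, ratio$mask)
  res <- ac_pooled(vlist, ks)
  keep <- res$pair_counts > 0
  structure(list(lags = ks[keep] * bs, rho = res$rho[keep],
                 pair_counts = res$pair_counts[keep]),
            class = "ac_curve")
}

#' @export
print.ac_curve <- function(x, ...) {
  cat(sprintf("<ac_curve> %d lags (%g..%g bp), rho[1] = %.3f\n",
              length(x$lags), min(x$lags), max(x$lags), x$rho[1]))
  invisible(x)
}

# mean rho over lags inside [lag_window[1], lag_window[2]] (bp, inclusive)
ac_window_mean <- function(vlist, bs, lag_window) {
  ks <- seq(ceiling(lag_window[1] / bs), floor(lag_window[2] / bs))
  if (length(ks) == 0L || ks[1] < 1L) stop("empty lag window", call. = FALSE)
  res <- ac_pooled(vlist, ks)
  ok <- res$pair_counts > 0
  if (!any(ok)) stop("no bin pairs in lag window", call. = FALSE)
  mean(res$rho[ok])
}

#' Permutation significance for the detection statistics
#'
#' Bins of the ratio track are randomly permuted within chromosomes —
#' destroying spatial structure and any alignment with the timing profile
#' while preserving the per-chromosome value distribution and the mask
#' pattern — and the statistic is recomputed for each permutation. The
#' one-sided add-one p-value is `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param ratio a `ratio_track`.
#' @param timing a `timing_profile` (required for `statistic = "timing_r"`).
#' @param n_perm number of permutations (>= 99).
#' @param statistic `"timing_r"` (Pearson correlation with the
#'   earliness-oriented timing signal) or `"ac_mean"` (mean autocorrelation
#'   over `lag_window`).
#' @param lag_window numeric `(lo, hi)` in base pairs; default
#'   `c(bin_size, 10 * bin_size)`.
#' @param seed integer seed for the permutation stream.
#' @return list with `p`, `observed`, and `null_values`.
#' @export
permutation_null <- function(ratio, timing = NULL, n_perm = 199,
                             statistic = c("timing_r", "ac_mean"),
                             lag_window = NULL, seed = 1) {
  stopifnot(inherits(ratio, "ratio_track"))
  statistic <- match.arg(statistic)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  bs <- ratio$layout$bin_size
  if (is.null(lag_window)) lag_window <- c(bs, 10 * bs)
  chrom_f <- factor(ratio$layout$bins$chrom, levels = ratio$layout$chromosomes$name)
  idx_by_chrom <- unname(split(seq_len(n_bins(ratio$layout)), chrom_f))
  unmasked_by_chrom <- lapply(idx_by_chrom, function(ix) ix[!ratio$mask[ix]])

  stat_fun <- if (statistic == "timing_r") {
    stopifnot(inherits(timing, "timing_profile"))
    if (!same_layout(ratio$layout, timing$layout)) {
      stop("ratio and timing are on different layouts", call. = FALSE)
    }
    sig <- 1 - timing$values
    function(values) {
      ok <- !is.na(values)
      if (sum(ok) < 10L) stop("fewer than 10 usable bins", call. = FALSE)
      x <- values[ok]; y <- sig[ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance", call. = FALSE)
      stats::cor(x, y)
    }
  } else {
    function(values) {
      vlist <- unname(split(values, chrom_f))
      ac_window_mean(vlist, bs, lag_window)
    }
  }

  observed <- stat_fun(ratio$values)
  null_values <- withr::with_seed(seed, {
    out <- numeric(n_perm)
    attempts <- 0L
    i <- 1L
    while (i <= n_perm) {
      if (attempts >= 10L * n_perm) {
        stop("permutation statistic failed too often", call. = FALSE)
      }
      attempts <- attempts + 1L
      perm <- ratio$values
      for (pos in unmasked_by_chrom) {
        if (length(pos) > 1L) perm[pos] <- perm[sample(pos)]
      }
      val <- tryCatch(stat_fun(perm), error = function(e) NA_real_)
      if (!is.na(val)) {
        out[i] <- val
        i <- i + 1L
      }
    }
    out
  })
  p <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  list(p = p, observed = observed, null_values = null_values)
}

#' Estimate the fraction of cells in S phase from a ratio track
#'
#' Fits the population copy-number model to the observed log2 ratio: a
#' fraction `p` of cells in S phase with uniform progression gives expected
#' relative copy number `c(x) = 1 + p (1 - T(x))`, and — because query and
#' reference are normalized to the same total signal — an expected log2
#' ratio of `log2(c(x) / M(p))` where `M(p) = 1 + p * mean(1 - T)` is the
#' genome-mean copy number (width-weighted over all bins). Omitting `M(p)`
#' would bias the estimate downward. `p` is fit by bounded least squares on
#' \[0,1\] (scalar search, tolerance 1e-6); the confidence interval is a
#' percentile bootstrap over bins.
#'
#' @param ratio a `ratio_track`.
#' @param timing a `timing_profile` on the same layout.
#' @param n_boot bootstrap replicates for the interval (0 skips it).
#' @param seed integer seed for the bootstrap.
#' @return an `s_phase_estimate`: list with `p_hat`, `ci_low`, `ci_high`,
#'   `n_boot`, `rss`, `n_bins_used`.
#' @export
estimate_s_fraction <- function(ratio, timing, n_boot = 200, seed = 1) {
  stopifnot(inherits(ratio, "ratio_track"), inherits(timing, "timing_profile"))
  if (!same_layout(ratio$layout, timing$layout)) {
    stop("ratio and timing are on different layouts", call. = FALSE)
  }
  ok <- !ratio$mask
  if (sum(ok) < 50L) stop("fewer than 50 usable bins", call. = FALSE)
  s_all <- 1 - timing$values
  w <- ratio$layout$bins$width
  sbar <- sum(s_all * w) / sum(w)
  s_use <- s_all[ok]
  obs <- ratio$values[ok]
  if (stats::sd(s_use) == 0) stop("degenerate timing profile (constant T)", call. = FALSE)

  fit_p <- function(obs_i, s_i) {
    rss <- function(p) sum((obs_i - log2((1 + p * s_i) / (1 + p * sbar)))^2)
    opt <- stats::optimize(rss, c(0, 1), tol = 1e-6)
    cand_p <- c(opt$minimum, 0, 1)
    cand_rss <- c(opt$objective, rss(0), rss(1))
    best <- which.min(cand_rss)
    c(p = cand_p[best], rss = cand_rss[best])
  }

  fit <- fit_p(obs, s_use)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(length(obs), replace = TRUE)
        fit_p(obs[ix], s_use[ix])[["p"]]
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    ci[1] <- min(ci[1], fit[["p"]])
    ci[2] <- max(ci[2], fit[["p"]])
  }
  structure(list(p_hat = unname(fit[["p"]]), ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, rss = unname(fit[["rss"]]),
                 n_bins_used = length(obs)),
            class = "s_phase_estimate")
}

#' @export
print.s_phase_estimate <- function(x, ...) {
  cat(sprintf("<s_phase_estimate> p_hat = %.4f [%.4f, %.4f] (%d bootstrap, %d bins)\n",
              x$p_hat, x$ci_low, x$ci_high, x$n_boot, x$n_bins_used))
  invisible(x)
}

#' Full replication-detection pipeline for one query/reference comparison
#'
#' Normalizes both tracks to the same total, forms the log2 ratio, and runs
#' the two detectors: correlation with the replication-timing profile (when
#' one is supplied) and mean spatial autocorrelation over a short-lag
#' window. Each statistic gets a within-chromosome permutation p-value; the
#' population is called replicating when the smallest p-value, Bonferroni
#' adjusted for the number of tests performed, is at or below `alpha`. A
#' ratio with (near-)zero variance — e.g. query and reference identical —
#' yields a degenerate not-replicating report rather than an error.
#'
#' @param query,reference `coverage_track`s on the same layout.
#' @param timing optional `timing_profile`.
#' @param alpha significance level for the decision.
#' @param config optional list overriding defaults: `min_ref`, `max_lag`
#'   (default 1e6 bp), `lag_window` (default `c(bin_size, 10 * bin_size)`),
#'   `n_perm` (199), `seed` (1), `ac_signal` (`"log2"`), `estimate`
#'   (TRUE when timing given), `n_boot` (100).
#' @return a `detection_report`: list with `pearson_r`, `n_bins_used`,
#'   `ac_curve`, `ac_statistic`, `p_timing`, `p_ac`, `decision`
#'   (`"replicating"` / `"not-replicating"`), `degenerate`, `estimate`,
#'   `ratio` (the intermediate `ratio_track`), `alpha`, `n_tests`,
#'   `totals` (normalization target).
#' @export
detect_replication <- function(query, reference, timing = NULL, alpha = 0.05,
                               config = list()) {
  stopifnot(inherits(query, "coverage_track"), inherits(reference, "coverage_track"))
  if (!same_layout(query$layout, reference$layout)) {
    stop("query and reference are on different layouts", call. = FALSE)
  }
  bs <- query$layout$bin_size
  cfg <- utils::modifyList(list(
    min_ref = NULL, max_lag = 1e6, lag_window = c(bs, 10 * bs),
    n_perm = 199, seed = 1, ac_signal = "log2",
    estimate = !is.null(timing), n_boot = 100
  ), config)

  target <- (query$total + reference$total) / 2
  qn <- normalize_total(query, target)
  rn <- normalize_total(reference, target)
  ratio <- log2_ratio(qn, rn, min_ref = cfg$min_ref)

  rep_base <- list(ratio = ratio, alpha = alpha, totals = target,
                   n_bins_used = sum(!ratio$mask), config = cfg,
                   pearson_r = NA_real_, p_timing = NA_real_,
                   ac_curve = NULL, ac_statistic = NA_real_, p_ac = NA_real_,
                   estimate = NULL)

  usable <- ratio$values[!ratio$mask]
  if (length(usable) < 10L || stats::sd(usable) < 1e-12) {
    rep_base$decision <- "not-replicating"
    rep_base$degenerate <- TRUE
    rep_base$n_tests <- 0L
    return(structure(rep_base, class = "detection_report"))
  }

  n_tests <- 1L + !is.null(timing)
  rep_base$degenerate <- FALSE
  rep_base$n_tests <- n_tests

  ac_ratio <- ratio
  if (cfg$ac_signal == "linear") {
    ac_ratio <- ratio_track(ratio$layout, 2^ratio$values, mask = ratio$mask)
  }
  rep_base$ac_curve <- autocorrelation(ratio, max_lag = cfg$max_lag,
                                       signal = cfg$ac_signal)
  in_win <- rep_base$ac_curve$lags >= cfg$lag_window[1] &
    rep_base$ac_curve$lags <= cfg$lag_window[2]
  rep_base$ac_statistic <- mean(rep_base$ac_curve$rho[in_win])
  pac <- permutation_null(ac_ratio, n_perm = cfg$n_perm, statistic = "ac_mean",
                          lag_window = cfg$lag_window, seed = cfg$seed + 1L)
  rep_base$p_ac <- pac$p

  if (!is.null(timing)) {
    pt <- pearson_timing(ratio, timing)
    rep_base$pearson_r <- pt$r
    ptest <- permutation_null(ratio, timing, n_perm = cfg$n_perm,
                              statistic = "timing_r", seed = cfg$seed + 2L)
    rep_base$p_timing <- ptest$p
    if (isTRUE(cfg$estimate)) {
      rep_base$estimate <- estimate_s_fraction(ratio, timing,
                                               n_boot = cfg$n_boot,
                                               seed = cfg$seed + 3L)
    }
  }

  p_min <- min(c(rep_base$p_ac, rep_base$p_timing), na.rm = TRUE)
  rep_base$p_adjusted <- min(1, p_min * n_tests)
  rep_base$decision <- if (rep_base$p_adjusted <= alpha) "replicating" else "not-replicating"
  structure(rep_base, class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  cat(sprintf("  decision: %s%s (alpha = %g, %d test%s)\n", x$decision,
              if (isTRUE(x$degenerate)) " [degenerate ratio]" else "",
              x$alpha, x$n_tests, if (x$n_tests == 1L) "" else "s"))
  cat(sprintf("  bins used: %d (of %d; %d masked)\n", x$n_bins_used,
              n_bins(x$ratio$layout), x$ratio$n_masked))
  if (!is.na(x$pearson_r)) {
    cat(sprintf("  timing correlation r = %.4f (perm p = %.4g)\n", x$pearson_r, x$p_timing))
  }
  if (!is.na(x$ac_statistic)) {
    cat(sprintf("  autocorrelation (lags %g-%g bp) = %.4f (perm p = %.4g)\n",
                x$config$lag_window[1], x$config$lag_window[2],
                x$ac_statistic, x$p_ac))
  }
  if (!is.null(x$estimate)) {
    cat(sprintf("  S-phase fraction estimate: %.3f [%.3f, %.3f]\n",
                x$estimate$p_hat, x$estimate$ci_low, x$estimate$ci_high))
  }
  invisible(x)
}

#' Flatten a detection report to a one-row data.frame
#' @param x a `detection_report`.
#' @param ... unused.
#' @return one-row data.frame suitable for TSV serialization.
#' @method as.data.frame detection_report
#' @export
as.data.frame.detection_report <- function(x, ...) {
  data.frame(
    decision = x$decision, degenerate = x$degenerate,
    pearson_r = x$pearson_r, p_timing = x$p_timing,
    ac_statistic = x$ac_statistic, p_ac = x$p_ac,
    p_adjusted = if (is.null(x$p_adjusted)) NA_real_ else x$p_adjusted,
    n_tests = x$n_tests, n_bins_used = x$n_bins_used,
    n_masked = x$ratio$n_masked, alpha = x$alpha,
    p_hat = if (is.null(x$estimate)) NA_real_ else x$estimate$p_hat,
    ci_low = if (is.null(x$estimate)) NA_real_ else x$estimate$ci_low,
    ci_high = if (is.null(x$estimate)) NA_real_ else x$estimate$ci_high
  )
}
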