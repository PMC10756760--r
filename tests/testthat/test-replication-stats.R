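make_sim_pair <- function(p_s, depth = 1e6, layout = default_layout(),
                          seed = 1, progression = "uniform") {
  timing <- simulate_timing(layout, seed = seed)
  q <- simulate_coverage(replicated_fraction(timing, population_model(p_s, progression)),
                         depth, seed = seed + 1)
  r <- simulate_coverage(replicated_fraction(timing, population_model(0)),
                         depth, seed = seed + 2)
  list(timing = timing, query = q, reference = r,
       ratio = log2_ratio(normalize_total(q, depth), normalize_total(r, depth)))
}

test_that("timing correlation matches the textbook sum formula and is oriented", {
  lay <- default_layout(2e6, 2, 1e4)
  tp <- simulate_timing(lay, seed = 4)

  # exact linear function of earliness gives r = 1
  rt <- ratio_track(lay, 0.3 * (1 - tp$values) + 0.1)
  res <- pearson_timing(rt, tp)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n, n_bins(lay))

  set.seed(5)
  for (i in 1:20) {
    rt <- random_ratio_track(lay, mask_frac = runif(1, 0, 0.3))
    res <- pearson_timing(rt, tp)
    ok <- !rt$mask
    expect_equal(res$r,
                 pearson_sum_formula(rt$values[ok], 1 - tp$values[ok]),
                 tolerance = 1e-12)
    expect_equal(res$n, sum(ok))
  }

  # fewer than 10 usable bins or zero variance -> error
  few <- ratio_track(lay, c(rnorm(9), rep(NA, n_bins(lay) - 9)))
  expect_error(pearson_timing(few, tp), "10 usable")
  expect_error(pearson_timing(ratio_track(lay, rep(0.2, n_bins(lay))), tp),
               "zero variance")
})

test_that("vectorized autocorrelation equals the brute-force pair oracle", {
  set.seed(42)
  for (i in 1:25) {
    lay <- random_layout(n_chrom = sample(1:4, 1))
    rt <- random_ratio_track(lay, mask_frac = runif(1, 0, 0.4))
    max_lag <- sample(3:20, 1) * 1e4
    curve <- autocorrelation(rt, max_lag = max_lag)
    ks <- seq_len(floor(max_lag / 1e4))
    oracle <- ac_brute_force(lay, rt$values, rt$mask, ks)
    keep <- oracle$pair_counts > 0
    expect_equal(curve$lags, ks[keep] * 1e4)
    expect_equal(curve$rho, oracle$rho[keep], tolerance = 1e-10)
    expect_equal(curve$pair_counts, oracle$pair_counts[keep])
    expect_true(all(abs(curve$rho) <= 1 + 1e-9))
    expect_true(all(diff(curve$lags) > 0))
  }
})

test_that("autocorrelation separates white noise from smooth signals", {
  lay1 <- default_layout(5e7, 1, 1e4)   # 5000 bins
  set.seed(8)
  noise <- ratio_track(lay1, rnorm(5000))
  curve <- autocorrelation(noise, max_lag = 2e5)
  expect_true(all(abs(curve$rho) < 0.05))

  # moving-average field (10-bin window): positive, decaying autocorrelation
  tp <- simulate_timing(lay1, correlation_length = 1e5, centromere_late = FALSE,
                        seed = 9)
  smooth <- ratio_track(lay1, tp$values)
  sc <- autocorrelation(smooth, max_lag = 2e5)
  expect_gt(sc$rho[1], sc$rho[10])
  expect_gt(sc$rho[10], 0)
  # no pairs span chromosome boundaries: 2-bin chromosomes have no lag-2 pairs
  tiny <- genome_layout(data.frame(name = c("A", "B"), length = c(2e4, 2e4)),
                        bin_size = 1e4)
  ct <- autocorrelation(ratio_track(tiny, c(1, 2, 4, 8)), max_lag = 3e4)
  expect_equal(ct$lags, 1e4)
  expect_equal(ct$pair_counts, 2)
})

test_that("detection statistics are shift- and scale-invariant", {
  sim <- make_sim_pair(0.3, seed = 31)
  base_r <- pearson_timing(sim$ratio, sim$timing)$r
  base_ac <- autocorrelation(sim$ratio, max_lag = 1e5)$rho
  for (tf in list(function(v) v + 3.7, function(v) 2.5 * v)) {
    rt <- ratio_track(sim$ratio$layout, tf(sim$ratio$values), mask = sim$ratio$mask)
    expect_equal(pearson_timing(rt, sim$timing)$r, base_r, tolerance = 1e-9)
    expect_equal(autocorrelation(rt, max_lag = 1e5)$rho, base_ac, tolerance = 1e-9)
  }
})

test_that("permutation p-values respect the add-one bound and detect signal", {
  sim <- make_sim_pair(1, seed = 17, progression = "beta")
  pt <- permutation_null(sim$ratio, sim$timing, n_perm = 99,
                         statistic = "timing_r", seed = 1)
  pa <- permutation_null(sim$ratio, n_perm = 99, statistic = "ac_mean", seed = 2)
  expect_equal(pt$p, 1 / 100)   # saturated significance for a fully S-phase population
  expect_equal(pa$p, 1 / 100)
  expect_gte(pt$p, 1 / (99 + 1))
  expect_equal(length(pt$null_values), 99L)
  # permutation destroys within-chromosome alignment (between-chromosome
  # level differences survive, so the null centre is only roughly zero)
  expect_lt(abs(mean(pt$null_values)), 0.2)
  expect_gt(pt$observed, max(pt$null_values) + 0.3)
  expect_error(permutation_null(sim$ratio, sim$timing, n_perm = 50), "n_perm")

  null <- make_sim_pair(0, seed = 23)
  pn <- permutation_null(null$ratio, null$timing, n_perm = 99,
                         statistic = "timing_r", seed = 3)
  expect_gt(pn$p, 0.01)
})

test_that("the S-fraction estimator inverts noiseless ratios exactly", {
  lay <- default_layout(2e7, 5, 1e4)
  tp <- simulate_timing(lay, seed = 2)
  s <- 1 - tp$values
  for (p in c(0.1, 0.3, 0.85)) {
    m <- 1 + p * mean(s)
    rt <- ratio_track(lay, log2((1 + p * s) / m))
    est <- estimate_s_fraction(rt, tp, n_boot = 0)
    expect_equal(est$p_hat, p, tolerance = 1e-4)
    expect_lt(est$rss, 1e-8)
  }
  # degenerate timing -> error
  flat <- timing_profile(lay, rep(0.5, n_bins(lay)))
  rt <- ratio_track(lay, rnorm(n_bins(lay)))
  expect_error(estimate_s_fraction(rt, flat, n_boot = 0), "degenerate timing")
  # too few bins -> error
  few <- ratio_track(lay, c(rnorm(40), rep(NA, n_bins(lay) - 40)))
  expect_error(estimate_s_fraction(few, tp, n_boot = 0), "50 usable")
})

test_that("the estimator is consistent on simulated data with bootstrap CIs", {
  lay <- default_layout(2e7, 5, 1e4)
  est <- local({
    sim <- make_sim_pair(0.3, layout = lay, seed = 101)
    estimate_s_fraction(sim$ratio, sim$timing, n_boot = 100, seed = 1)
  })
  expect_lt(abs(est$p_hat - 0.3), 0.05)
  expect_true(est$ci_low <= est$p_hat && est$p_hat <= est$ci_high)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  # p_s = 0: estimate pinned near zero
  sim0 <- make_sim_pair(0, layout = lay, seed = 102)
  est0 <- estimate_s_fraction(sim0$ratio, sim0$timing, n_boot = 0)
  expect_lte(est0$p_hat, 0.05)
})

test_that("detect_replication reaches the right verdicts end to end", {
  # identical query and reference: degenerate, not-replicating
  lay <- default_layout(2e6, 2, 1e4)
  tr <- coverage_track(lay, rpois(n_bins(lay), 100))
  rep0 <- detect_replication(tr, tr)
  expect_equal(rep0$decision, "not-replicating")
  expect_true(rep0$degenerate)
  expect_true(is.na(rep0$p_ac))

  sim <- make_sim_pair(1, seed = 55, progression = "beta")
  rep1 <- detect_replication(sim$query, sim$reference, sim$timing,
                             config = list(n_perm = 99, seed = 5))
  expect_equal(rep1$decision, "replicating")
  expect_false(rep1$degenerate)
  expect_equal(rep1$n_tests, 2L)
  expect_gt(rep1$pearson_r, 0.8)
  expect_lte(rep1$p_adjusted, 0.05)
  expect_gt(rep1$estimate$p_hat, 0.9)
  # intermediate ratio track is retrievable and consistent
  expect_s3_class(rep1$ratio, "ratio_track")
  expect_equal(rep1$n_bins_used, sum(!rep1$ratio$mask))

  simnull <- make_sim_pair(0, seed = 56)
  rep2 <- detect_replication(simnull$query, simnull$reference, simnull$timing,
                             config = list(n_perm = 99, seed = 5, estimate = FALSE))
  expect_equal(rep2$decision, "not-replicating")
  expect_null(rep2$estimate)

  # without a timing profile only the autocorrelation test runs
  rep3 <- detect_replication(sim$query, sim$reference,
                             config = list(n_perm = 99, seed = 5))
  expect_equal(rep3$n_tests, 1L)
  expect_true(is.na(rep3$pearson_r))
  expect_equal(rep3$decision, "replicating")

  flat <- as.data.frame(rep1)
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$decision, "replicating")

  other <- default_layout(2e6, 2, 1e4)
  mism <- default_layout(4e6, 2, 1e4)
  expect_error(detect_replication(tr, coverage_track(mism, rep(1, n_bins(mism)))),
               "layout")
})

test_that("linear-scale autocorrelation is available as an option", {
  sim <- make_sim_pair(1, seed = 77, progression = "beta")
  lin <- autocorrelation(sim$ratio, max_lag = 1e5, signal = "linear")
  log <- autocorrelation(sim$ratio, max_lag = 1e5)
  expect_equal(length(lin$rho), length(log$rho))
  expect_gt(lin$rho[1], 0.5)  # the replication signal shows on both scales
})
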