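# Independent oracles and fixture builders shared across test files.

# Brute-force pooled lag autocorrelation, written directly from the
# definition with an explicit double loop over bin pairs. Kept deliberately
# independent of the package's vectorized implementation.
ac_brute_force <- function(layout, values, mask, ks) {
  chrom <- as.character(layout$bins$chrom)
  v <- values
  v[mask] <- NA_real_
  # per-chromosome centering on unmasked bins
  for (cn in unique(chrom)) {
    ix <- which(chrom == cn)
    m <- mean(v[ix], na.rm = TRUE)
    v[ix] <- v[ix] - m
  }
  un <- which(!is.na(v))
  varg <- sum(v[un]^2) / length(un)
  rho <- numeric(length(ks))
  cnt <- numeric(length(ks))
  n <- length(v)
  for (j in seq_along(ks)) {
    k <- ks[j]
    num <- 0
    np <- 0
    for (i in seq_len(n)) {
      ii <- i + k
      if (ii > n) next
      if (chrom[i] != chrom[ii]) next
      if (is.na(v[i]) || is.na(v[ii])) next
      num <- num + v[i] * v[ii]
      np <- np + 1
    }
    rho[j] <- if (np > 0) (num / np) / varg else NA_real_
    cnt[j] <- np
  }
  list(rho = rho, pair_counts = cnt)
}

# Textbook sum formula for the Pearson correlation coefficient.
pearson_sum_formula <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Random multi-chromosome layout for property tests.
random_layout <- function(n_chrom = 3, max_bins_per_chrom = 80, bin_size = 1e4) {
  nb <- sample.int(max_bins_per_chrom, n_chrom) + 4L
  genome_layout(
    data.frame(name = paste0("Chr", seq_len(n_chrom)), length = nb * bin_size),
    bin_size = bin_size
  )
}

# Random ratio track with an optional random mask on a given layout.
random_ratio_track <- function(layout, mask_frac = 0) {
  n <- n_bins(layout)
  mask <- rep(FALSE, n)
  if (mask_frac > 0) mask[sample.int(n, ceiling(mask_frac * n))] <- TRUE
  ratio_track(layout, ifelse(mask, NA_real_, rnorm(n)), mask = mask)
}

# Minimal indexed BAM built from literal SAM records (text in, binary made
# at test time). Returns the BAM path.
make_test_bam <- function(dir, records,
                          sq = "@SQ\tSN:Chr1\tLN:100000") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# One single-end SAM record with the given flag, 1-based pos and 50M cigar.
sam_read <- function(name, flag, pos, chrom = "Chr1", cigar = "50M") {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          name, flag, chrom, pos, cigar,
          paste(rep("A", 50), collapse = ""), paste(rep("I", 50), collapse = ""))
}
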