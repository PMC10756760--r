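test_that("chrom.sizes parsing honors file order and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".chrom.sizes")
  writeLines(c("Chr3\t23459830"), path)
  lay <- read_chrom_sizes(path)
  expect_equal(lay$chromosomes$name, "Chr3")
  expect_equal(lay$chromosomes$length, 23459830)

  writeLines(c("Chr1 100000", "Chr2 50000"), path)
  lay <- read_chrom_sizes(path, bin_size = 1e4)
  expect_equal(lay$chromosomes$length, c(100000, 50000))
  expect_equal(n_bins(lay), 15L)

  writeLines("Chr1 0", path)
  expect_error(read_chrom_sizes(path), "line 1")
  writeLines(c("Chr1 100", "Chr1 200"), path)
  expect_error(read_chrom_sizes(path), "duplicate")
  writeLines("Chr1", path)
  expect_error(read_chrom_sizes(path), "malformed")
})

test_that("bin lattice has ceil(length/bin_size) bins and a true-width tail", {
  lay <- genome_layout(data.frame(name = "Chr1", length = 25000), bin_size = 1e4)
  expect_equal(n_bins(lay), 3L)
  expect_equal(lay$bins$width, c(1e4, 1e4, 5e3))
  expect_equal(lay$bins$end[3], 25000)
})

test_that("bedGraph records are apportioned to bins by overlap fraction", {
  lay <- genome_layout(data.frame(name = c("Chr1", "Chr2"),
                                  length = c(100000, 50000)), bin_size = 1e4)
  path <- withr::local_tempfile(fileext = ".bedGraph")

  writeLines("Chr1\t0\t10000\t5", path)
  tr <- read_bedgraph(path, lay)
  expect_equal(tr$values[1], 5)
  expect_equal(tr$total, 5)

  writeLines("Chr1\t5000\t15000\t4", path)
  tr <- read_bedgraph(path, lay)
  expect_equal(tr$values[1:2], c(2, 2))

  # unsorted input, second chromosome
  writeLines(c("Chr2\t0\t10000\t1", "Chr1\t0\t10000\t2"), path)
  tr <- read_bedgraph(path, lay)
  expect_equal(tr$values[1], 2)
  expect_equal(tr$values[11], 1)

  writeLines("ChrX\t0\t10000\t1", path)
  expect_error(read_bedgraph(path, lay), "unknown chromosome")
  writeLines("Chr2\t45000\t55000\t1", path)
  expect_error(read_bedgraph(path, lay), "beyond chromosome end")
  writeLines(c("Chr1\t0\t10000\t1", "Chr1\t5000\t15000\t1"), path)
  expect_error(read_bedgraph(path, lay), "overlapping")
})

test_that("alignment binning counts fragment midpoints and honors flags", {
  lay <- genome_layout(data.frame(name = "Chr1", length = 100000), bin_size = 1e4)
  dir <- withr::local_tempdir()
  # three reads with midpoints in bin 8 (0-based bin 7), plus one duplicate,
  # one secondary and one unmapped record
  bam <- make_test_bam(dir, c(
    sam_read("r1", 0L, 70001),
    sam_read("r2", 0L, 70501),
    sam_read("r3", 16L, 79900),
    sam_read("dup", 1024L, 20001),
    sam_read("sec", 256L, 30001),
    sam_read("unm", 4L, 40001)
  ))
  tr <- bin_alignments(bam, lay, dedupe = TRUE)
  expect_equal(tr$values[8], 3)
  expect_equal(tr$total, 3)
  tr2 <- bin_alignments(bam, lay, dedupe = FALSE)
  expect_equal(tr2$values[3], 1)
  expect_equal(tr2$total, 4)

  empty <- make_test_bam(file.path(dir, "e"), character(0))
  tr0 <- bin_alignments(empty, lay)
  expect_equal(tr0$total, 0)
  expect_equal(length(tr0$values), 10L)

  file.remove(paste0(bam, ".bai"))
  expect_error(bin_alignments(bam, lay), "index")
})

test_that("depth normalization is linear, exact, and idempotent", {
  lay <- genome_layout(data.frame(name = "Chr1", length = 30000), bin_size = 1e4)
  tr <- coverage_track(lay, c(2, 4, 6))
  n1 <- normalize_total(tr, 3)
  expect_equal(n1$values, c(0.5, 1.0, 1.5))
  expect_equal(n1$total, 3, tolerance = 1e-12)
  expect_equal(normalize_total(n1, 3)$values, n1$values, tolerance = 1e-12)
  expect_equal(normalize_total(tr, 12)$values, tr$values)
  expect_error(normalize_total(coverage_track(lay, c(0, 0, 0)), 1), "all-zero")
})

test_that("rebin merges within chromosomes and conserves totals exactly", {
  lay <- genome_layout(data.frame(name = c("Chr1", "Chr2"),
                                  length = c(70000, 40000)), bin_size = 1e4)
  set.seed(1)
  tr <- coverage_track(lay, rpois(11, 50))
  expect_identical(rebin(tr, 1), tr)
  r3 <- rebin(tr, 3)
  # Chr1: 7 bins -> groups 3,3,1; Chr2: 4 bins -> groups 3,1
  expect_equal(n_bins(r3$layout), 5L)
  expect_equal(r3$values[1], sum(tr$values[1:3]))
  expect_equal(r3$values[3], tr$values[7])          # trailing partial group
  expect_equal(r3$values[4], sum(tr$values[8:10]))  # no cross-chromosome group
  expect_equal(r3$total, tr$total)
  for (f in c(2, 5, 7, 11)) expect_equal(rebin(tr, f)$total, tr$total)
  expect_equal(rebin(tr, 10)$layout$bin_size, 1e5)
})

test_that("log2 ratio doubles map to 1 and unusable bins are masked", {
  lay <- genome_layout(data.frame(name = "Chr1", length = 4e4), bin_size = 1e4)
  q <- coverage_track(lay, c(4, 2, 2, 0))
  r <- coverage_track(lay, c(2, 2, 0, 2))
  rt <- log2_ratio(q, r, min_ref = 0.5)
  expect_equal(rt$values[1], 1)      # doubled coverage -> log2 ratio 1
  expect_equal(rt$values[2], 0)
  expect_true(rt$mask[3])            # reference below threshold
  expect_true(rt$mask[4])            # zero query
  expect_equal(rt$n_masked, 2L)

  same <- log2_ratio(q, q, min_ref = 0.5)
  expect_equal(same$values[!same$mask], rep(0, sum(!same$mask)))

  other <- genome_layout(data.frame(name = "Chr1", length = 5e4), bin_size = 1e4)
  expect_error(log2_ratio(q, coverage_track(other, rep(1, 5))), "layout")
})

test_that("interval masks hit exactly the overlapping bins", {
  lay <- genome_layout(data.frame(name = c("Chr1", "Chr2"),
                                  length = c(1e5, 1e5)), bin_size = 1e4)
  rt <- ratio_track(lay, rnorm(20))
  expect_equal(apply_mask(rt, mask_set(data.frame(chrom = character(0),
                                                  start = numeric(0),
                                                  end = numeric(0))))$values,
               rt$values)
  whole <- mask_set(data.frame(chrom = c("Chr1", "Chr2"), start = 0, end = 1e5))
  expect_equal(apply_mask(rt, whole)$n_masked, 20L)
  first10 <- apply_mask(rt, mask_set(data.frame(chrom = "Chr1", start = 0, end = 1e5)))
  expect_equal(first10$n_masked, 10L)
  expect_equal(which(first10$mask), 1:10)
  # partial overlap of a single bin still masks that bin
  one <- apply_mask(rt, mask_set(data.frame(chrom = "Chr2", start = 15000, end = 15001)))
  expect_equal(which(one$mask), 12L)
  expect_error(mask_set(data.frame(chrom = "Chr1", start = 10, end = 10)), "start < end")
  expect_error(apply_mask(rt, mask_set(data.frame(chrom = "Chr1", start = 0, end = 2e5))),
               "bounds")
})

test_that("coverage tracks round-trip exactly through bedGraph", {
  lay <- genome_layout(data.frame(name = c("Chr1", "Chr2"),
                                  length = c(95000, 40000)), bin_size = 1e4)
  set.seed(7)
  tr <- coverage_track(lay, rpois(n_bins(lay), 100), label = "x")
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(tr, path)
  back <- read_bedgraph(path, lay, label = "x")
  expect_identical(back$values, tr$values)
  expect_identical(back$total, tr$total)

  rt <- ratio_track(lay, c(rnorm(11), NA, NA, NA))
  write_track(rt, path)
  expect_equal(length(readLines(path)), n_bins(lay) - 3L)

  empty <- genome_layout(data.frame(name = character(0), length = numeric(0)),
                         bin_size = 1e4)
  expect_error(write_track(coverage_track(empty, numeric(0)), path), "empty")
})
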