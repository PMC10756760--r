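---
title: "Detecting ongoing DNA replication from sequencing coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ongoing DNA replication from sequencing coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the signal

A cell that is part-way through S phase carries two copies of the genomic
regions it has already replicated and one copy of everything else. In
whole-genome sequencing of a population, replicated regions therefore draw
up to double the read depth of unreplicated regions. `repliseek` turns this
into a statistical test: given binned coverage for a *query* population and
a non-replicating *reference*, does the query show the copy-number
footprint of ongoing replication? The motivating use case is deciding
whether a sorted nuclei population (for example, sperm nuclei from mature
pollen) contains any replicating cells at all, where a negative answer is
only meaningful together with a bound on how small a replicating
subpopulation could have been missed.

Two detectors are used, deliberately complementary:

1. **Timing correlation.** Replication proceeds in a characteristic order;
   if a replication-timing reference is available, the per-bin log2
   query/reference coverage ratio should correlate with it (early regions
   over-represented). We report the Pearson correlation between the ratio
   and an *earliness* signal `1 − T`, where `T` is the per-bin timing
   quantile (0 = earliest).
2. **Spatial autocorrelation.** Even without any timing reference,
   replication timing is spatially smooth — nearby regions replicate at
   similar times — so a partially replicated population shows positive
   autocorrelation of its coverage ratio between nearby bins, whatever the
   replication order. White multinomial sampling noise does not.

## The population copy-number model

Let `T(x) ∈ [0,1]` be the timing quantile of bin `x`, `p` the fraction of
cells in S phase, and let each replicating cell sit at progression
`s ∈ [0,1]` drawn from a *progression law*. Under the quantile-threshold
model, a cell at progression `s` has replicated exactly the bins with
`T(x) ≤ s`. The expected relative copy number is then

    c(x) = 1 + r(x),   r(x) = p · P(s ≥ T(x)),

so `c ∈ [1,2]` and, for the Uniform(0,1) law of an unsynchronized S-phase
population, `r(x) = p · (1 − T(x))`. A Beta law (default Beta(5,5))
represents a synchronized culture concentrated in mid-S. We model counts,
not forks: explicit origin-firing kinetics would add parameters without
changing any of the count-level statistics the detectors see.

Sequencing is modeled as a multinomial with a fixed number of fragments
(`depth`) and per-bin probabilities proportional to
`c(x) · width(x)/bin_size · mappability(x)`. Conditioning on the total
matches the common practice of down-sampling libraries to a fixed fragment
count before comparison; it is why both tracks are normalized to the same
total signal before the ratio is taken. Mappability defaults to uniform —
the hook exists because real coverage is not uniform, but estimating
mappability is out of scope.

## What the simulator does and does not emulate

`simulate_timing()` builds the timing landscape as a per-chromosome moving
average of white noise (window = `correlation_length / bin_size` bins,
reflected at chromosome ends), optionally with a late-replicating bump over
the central 20% of each chromosome standing in for pericentromeric
heterochromatin, then rank-transforms genome-wide to uniform quantiles.
This reproduces the two features the detectors rely on — smoothness along
chromosomes and a defined replication order — but none of the sequence-level
structure of real data: no GC or fragmentation bias, no mappability holes,
no copy-number variants, no read-level artifacts (duplicate marking and
mapping are upstream concerns; the package honors duplicate flags and
nothing more). Passing tests on simulated data therefore demonstrate the
statistical behavior of the method under its own noise model, not
robustness to platform artifacts — on real data, inspecting the masked-bin
count and the ratio track remains the analyst's job.

Defaults chosen once for the standard conditions: a 10 Mb genome in five
2 Mb chromosomes at 10-kb bins (1000 bins — large enough for stable
statistics, small enough that hundreds of replicates run in minutes),
depth 10^6 fragments per sample (≈1000 per bin, the regime where log-ratio
noise is a few percent), timing correlation length 1 Mb (a sizeable
fraction of a chromosome arm, as observed timing domains are). The three
stain-intensity subfractions use illustrative `p` = 0.05/0.2/0.5; no
instrument gating is modeled.

## Statistics: conventions and numerical choices

**Binning and ratios.** Coordinates are 0-based half-open (bedGraph
native). Bin lattices come from a chrom.sizes genome; the final bin of each
chromosome may be partial and keeps its true width, which the simulator
respects when placing reads. Coarse profiles are made by summing counts
into wider bins and then taking the ratio (sum-then-ratio), not by
averaging fine-scale log ratios — the summed estimator has strictly lower
variance. Bins with reference coverage below `min_ref` (default 25% of the
genome-wide mean per-bin reference count) or zero query are masked, never
pseudocounted, and the masked count is always reported.

**Autocorrelation.** The log2 ratio is mean-centered per chromosome (so
between-chromosome level differences cannot masquerade as spatial
structure); for each lag `d = k · bin_size` the products of all
within-chromosome unmasked pairs at distance `d` are summed, pooled across
chromosomes (summing numerators and pair counts, dividing once — pair-count
weighting, so short chromosomes cannot dominate) and scaled by the
genome-wide variance of the centered signal. No pair spans a chromosome
boundary or a masked bin. The log2 scale is the default signal; a linear
option exists for sensitivity checks and leads to the same conclusions on
simulated data. The detection statistic is the mean autocorrelation over
lags from one to ten bin widths (10–100 kb at 10-kb bins): short enough to
sit well inside a timing domain, long enough to average ten estimates.

**Significance.** The study design has no replicates to build a null from,
so significance is by permutation: bin values are shuffled *within*
chromosomes, destroying spatial structure and timing alignment while
preserving the value distribution and the mask pattern; the one-sided
add-one p-value is `(1 + #{null ≥ observed})/(n_perm + 1)` (so never
smaller than `1/(n_perm+1)`; default `n_perm = 199`). Within-chromosome
shuffling deliberately preserves between-chromosome level differences,
which is also why the permutation null of the timing correlation is not
exactly centered at zero for strong signals — under the null hypothesis of
no replication the bins are exchangeable and both tests are calibrated,
which the test suite verifies against the exact binomial interval. The
combined call applies Bonferroni over the (at most two) tests performed: a
population is called replicating when the smaller p-value times the number
of tests is ≤ α. A degenerate ratio (identical query and reference) is
reported as not-replicating with a `degenerate` flag rather than an error.

**S-fraction estimation.** Because both tracks carry the same total
signal, the observed ratio is mean-centered in linear space; the fitted
model is therefore

    log2 ratio(x) ≈ log2[ (1 + p(1 − T(x))) / M(p) ],
    M(p) = 1 + p · mean(1 − T)   (width-weighted over all bins),

and omitting `M(p)` would bias `p̂` downward. The single parameter `p` is
fit by bounded scalar least squares on [0,1] (golden-section/parabolic
search, tolerance 1e-6, endpoints checked explicitly so boundary optima are
exact), with a percentile bootstrap over bins for the interval. The Uniform
law is assumed in the fit; for synchronized populations the fitted `p`
remains a useful index of S-phase content but its progression profile is
mis-specified, which is why the detector, not the estimator, makes the
replicating/not-replicating call.

**Ties and orientation.** Timing quantiles use average ranks for ties.
External timing references (e.g. EdU enrichment from early-S cells, where
high signal = early replication) are converted with
`as_timing_profile(..., orientation = "early_high")`; sign conventions are
fixed so that a replicating query gives a *positive* correlation.

## Power analysis

`run_sweep()` simulates query/reference pairs over a grid of S-phase
fractions and depths (replicate seeds derived from the spec seed by
counter, matched across grid cells so power curves are smooth in `p`), runs
the full detector plus estimator on each, and tabulates rejection rates and
estimator moments; `minimal_detectable_fraction()` interpolates the
smallest `p` reaching a target power. At the standard conditions (10 Mb,
10-kb bins, depth 10^6) the combined detector reaches 80% power below
`p ≈ 0.02`, so a negative result excludes all but a very small replicating
subpopulation; at depth 10^5 the bound is weaker — the tables produced by
`analysis/03_power.R` quantify this. The default sweep sizes (20–50
replicates per cell) keep a full sweep in the minutes range on one core;
they are statistical-reporting choices, and can be raised for publication-
grade tables.

## Known limitations

- The estimator assumes the Uniform progression law and a single
  homogeneous S-phase subpopulation; mixtures of synchronized cohorts are
  detected but their `p̂` is an effective, not literal, fraction.
- Masking handles low-coverage bins but the simulator's uniform
  mappability means masking paths are only lightly exercised by synthetic
  data; centromere exclusion is available via `mask_set()` but off by
  default, since the detectors are robust to including them.
- Permutation p-values have resolution `1/(n_perm+1)`; Bonferroni over two
  correlated tests is conservative.
- The bedGraph reader requires non-overlapping records (as produced by
  standard binned-coverage tools) and apportions partially overlapping
  records by overlap fraction — it is not a general interval-arithmetic
  engine.
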