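#' Population models of S-phase content
#'
#' A population is summarized by the fraction `p_s` of its cells that are in
#' S phase and by the distribution ("progression law") of how far through S
#' phase each replicating cell has progressed, on \[0,1\]. Under the
#' quantile-threshold replication model, a cell at progression `s` has
#' replicated exactly the bins whose timing quantile `T` satisfies
#' `T <= s` — earlier-replicating regions are copied first.
#'
#' The default Uniform(0,1) law describes an unsynchronized S-phase
#' population (equal time spent per unit of progression); a Beta law
#' concentrated mid-S describes chemically synchronized cultures released
#' into S phase.
#'
#' @param p_s fraction of cells in S phase, in \[0,1\].
#' @param progression `"uniform"` or `"beta"`.
#' @param shape1,shape2 Beta parameters (used when `progression = "beta"`).
#' @param label sample label.
#' @return a `population_model`.
#' @export
population_model <- function(p_s, progression = c("uniform", "beta"),
                             shape1 = 5, shape2 = 5, label = "") {
  progression <- match.arg(progression)
  if (!is.finite(p_s) || p_s < 0 || p_s > 1) stop("p_s must lie in [0, 1]", call. = FALSE)
  structure(list(p_s = p_s, progression = progression,
                 shape1 = shape1, shape2 = shape2, label = label),
            class = "population_model")
}

# P(s >= t) under the progression law, vectorized over t in [0,1]
progression_survival <- function(population, t) {
  switch(population$progression,
         uniform = 1 - t,
         beta = 1 - stats::pbeta(t, population$shape1, population$shape2))
}

#' Simulate a smooth replication-timing landscape
#'
#' Per chromosome, a latent field is built as a moving average of white
#' noise (window = `correlation_length / bin_size` bins, forced odd,
#' reflected at chromosome ends), optionally with a late-replicating bump
#' over the central 20% of each chromosome emulating centromeric
#' heterochromatin. The latent field is then rank-transformed genome-wide to
#' quantiles in \[0,1\] (average ranks for ties); 0 = earliest-replicating.
#'
#' @param layout a `genome_layout` with bin size set.
#' @param correlation_length smoothness scale in base pairs
#'   (>= `bin_size`); replication timing is spatially smooth because nearby
#'   regions replicate at similar times.
#' @param centromere_late add the late-replicating central bump.
#' @param seed integer seed; the profile is a deterministic function of it.
#' @return a `timing_profile`.
#' @export
simulate_timing <- function(layout, correlation_length = 1e6,
                            centromere_late = TRUE, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  if (correlation_length < layout$bin_size) {
    stop("correlation_length must be >= bin_size", call. = FALSE)
  }
  nb <- bins_per_chrom(layout)
  latent <- withr::with_seed(seed, {
    unlist(lapply(nb, function(n) {
      w <- max(1L, round(correlation_length / layout$bin_size))
      if (w %% 2L == 0L) w <- w + 1L
      w <- min(w, 2L * n - 1L)
      z <- stats::rnorm(n)
      pad <- (w - 1L) %/% 2L
      zp <- if (pad > 0L) c(rev(z[seq_len(pad)]), z, rev(z[seq(n - pad + 1L, n)])) else z
      y <- as.numeric(stats::filter(zp, rep(1 / w, w), sides = 2))
      y <- y[seq(pad + 1L, pad + n)]
      if (centromere_late) {
        lo <- floor(0.4 * n) + 1L
        hi <- ceiling(0.6 * n)
        idx <- seq(lo, hi)
        bump <- 4 * stats::sd(y) * (0.5 - 0.5 * cos(2 * pi * (idx - lo) / max(1L, hi - lo)))
        y[idx] <- y[idx] + bump
      }
      y
    }))
  })
  q <- (rank(latent, ties.method = "average") - 0.5) / length(latent)
  timing_profile(layout, q)
}

#' Expected per-bin copy number of a cell population
#'
#' Under the quantile-threshold model, the fraction of cells in which bin
#' `x` is replicated is `r(x) = p_s * P(s >= T(x))` with `s` drawn from the
#' progression law; the expected relative copy number is `c(x) = 1 + r(x)`,
#' so `c` lies in \[1,2\]: replicated DNA yields double the coverage of
#' unreplicated DNA.
#'
#' @param timing a `timing_profile`.
#' @param population a `population_model`.
#' @return a `copy_number_field` with elements `layout`, `c` (expected
#'   relative copy number) and `r` (per-bin replicated fraction).
#' @export
replicated_fraction <- function(timing, population) {
  stopifnot(inherits(timing, "timing_profile"), inherits(population, "population_model"))
  r <- population$p_s * progression_survival(population, timing$values)
  structure(list(layout = timing$layout, c = 1 + r, r = r,
                 label = population$label),
            class = "copy_number_field")
}

#' Sample finite-depth sequencing coverage from a copy-number field
#'
#' Read counts are drawn from a multinomial with `depth` trials and per-bin
#' probabilities proportional to `c(x) * width(x) / bin_size *
#' mappability(x)`; the track total equals `depth` exactly, matching a
#' library down-sampled to a fixed number of fragments.
#'
#' @param field a `copy_number_field`.
#' @param depth total number of fragments to place (>= 1).
#' @param mappability optional per-bin weight in (0, 1\]; default uniform.
#' @param seed integer seed.
#' @param label sample label.
#' @return a `coverage_track` of counts summing to `depth`.
#' @export
simulate_coverage <- function(field, depth, mappability = NULL, seed = 1,
                              label = field$label) {
  stopifnot(inherits(field, "copy_number_field"))
  depth <- as.numeric(depth)
  if (!is.finite(depth) || depth < 1) stop("depth must be >= 1", call. = FALSE)
  layout <- field$layout
  w <- layout$bins$width / layout$bin_size
  if (is.null(mappability)) mappability <- rep(1, n_bins(layout))
  if (length(mappability) != n_bins(layout) || any(mappability <= 0 | mappability > 1)) {
    stop("mappability must be one weight in (0, 1] per bin", call. = FALSE)
  }
  prob <- field$c * w * mappability
  if (sum(prob) <= 0) stop("all-zero sampling probabilities", call. = FALSE)
  counts <- withr::with_seed(seed, stats::rmultinom(1L, size = depth, prob = prob))[, 1L]
  coverage_track(layout, counts, label = label)
}

#' Simulation scenarios: multi-sample designs
#'
#' A scenario bundles a layout, a timing profile, one population per output
#' sample, a sequencing depth, and a seed. Presets mirror the sample designs
#' the method is used on: `"g1_only"` (no S-phase cells, `p_s` = 0, the
#' negative control and the usual reference), `"synchronized_s"` (`p_s` = 1
#' with Beta(5,5) mid-S progression, a synchronized S-phase culture — the
#' positive control), and `"pi_fractions"` (three subpopulations of
#' increasing `p_s` = 0.05/0.2/0.5, emulating sorting by DNA-stain
#' intensity; the values are illustrative, no instrument gates are modeled).
#'
#' @param preset one of `"g1_only"`, `"synchronized_s"`, `"pi_fractions"`.
#' @param layout a `genome_layout`; default [default_layout()].
#' @param timing optional `timing_profile`; simulated from the scenario seed
#'   when omitted.
#' @param depth fragments per sample.
#' @param seed integer scenario seed; per-sample substreams are derived from
#'   it deterministically.
#' @param correlation_length timing smoothness passed to [simulate_timing()].
#' @return a `simulation_scenario`.
#' @export
scenario_preset <- function(preset = c("g1_only", "synchronized_s", "pi_fractions"),
                            layout = default_layout(), timing = NULL,
                            depth = 1e6, seed = 1, correlation_length = 1e6) {
  preset <- match.arg(preset)
  populations <- switch(preset,
    g1_only = list(population_model(0, "uniform", label = "g1_only")),
    synchronized_s = list(population_model(1, "beta", 5, 5, label = "synchronized_s")),
    pi_fractions = list(
      population_model(0.05, "uniform", label = "pi_low"),
      population_model(0.20, "uniform", label = "pi_mid"),
      population_model(0.50, "uniform", label = "pi_high")
    ))
  simulation_scenario(layout, populations, timing = timing, depth = depth,
                      seed = seed, correlation_length = correlation_length,
                      label = preset)
}

#' @rdname scenario_preset
#' @param populations list of `population_model`s, one per output sample.
#' @param mappability optional per-bin weights shared by all samples.
#' @param label scenario label.
#' @export
simulation_scenario <- function(layout, populations, timing = NULL, depth = 1e6,
                                seed = 1, correlation_length = 1e6,
                                mappability = NULL, label = "scenario") {
  stopifnot(inherits(layout, "genome_layout"), length(populations) >= 1L)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  structure(list(layout = layout, populations = populations, timing = timing,
                 depth = depth, seed = as.integer(seed),
                 correlation_length = correlation_length,
                 mappability = mappability, label = label),
            class = "simulation_scenario")
}

#' Run a simulation scenario
#'
#' Simulates (or reuses) the timing profile, derives each population's
#' copy-number field, and samples one coverage track per population from an
#' independent substream of the scenario seed.
#'
#' @param scenario a `simulation_scenario`.
#' @return a list with elements `tracks` (named list of `coverage_track`),
#'   `fields` (matching `copy_number_field`s), `timing`, and `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  npop <- length(scenario$populations)
  seeds <- withr::with_seed(scenario$seed,
                            sample.int(.Machine$integer.max - 1L, npop + 1L))
  timing <- scenario$timing
  if (is.null(timing)) {
    timing <- simulate_timing(scenario$layout, scenario$correlation_length,
                              seed = seeds[npop + 1L])
  }
  fields <- lapply(scenario$populations, replicated_fraction, timing = timing)
  labels <- vapply(scenario$populations, function(p) p$label, "")
  labels[!nzchar(labels)] <- paste0("sample", which(!nzchar(labels)))
  tracks <- lapply(seq_len(npop), function(i) {
    simulate_coverage(fields[[i]], depth = scenario$depth,
                      mappability = scenario$mappability,
                      seed = seeds[i], label = labels[i])
  })
  names(tracks) <- labels
  names(fields) <- labels
  list(tracks = tracks, fields = fields, timing = timing, scenario = scenario)
}

#' Read a simulation scenario from a YAML config
#'
#' Keys: `genome` (path to chrom.sizes) or `genome_size`/`n_chrom`,
#' `bin_size`, `correlation_length`, `depth`, `seed`, and either `preset` or
#' a `populations` list of `{p_s, progression, shape1, shape2, label}`.
#'
#' @param path YAML file.
#' @return a `simulation_scenario`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  bin_size <- as.numeric(cfg[["bin_size"]] %||% 1e4)
  layout <- if (!is.null(cfg[["genome"]])) {
    read_chrom_sizes(cfg[["genome"]], bin_size = bin_size)
  } else {
    default_layout(genome_size = as.numeric(cfg[["genome_size"]] %||% 1e7),
                   n_chrom = cfg[["n_chrom"]] %||% 5, bin_size = bin_size)
  }
  depth <- as.numeric(cfg[["depth"]] %||% 1e6)
  seed <- cfg[["seed"]] %||% 1
  clen <- as.numeric(cfg[["correlation_length"]] %||% 1e6)
  if (!is.null(cfg[["preset"]])) {
    return(scenario_preset(cfg[["preset"]], layout = layout, depth = depth,
                           seed = seed, correlation_length = clen))
  }
  if (is.null(cfg[["populations"]])) {
    stop("config needs 'preset' or 'populations'", call. = FALSE)
  }
  pops <- lapply(cfg[["populations"]], function(p) {
    population_model(p[["p_s"]], p[["progression"]] %||% "uniform",
                     shape1 = p[["shape1"]] %||% 5, shape2 = p[["shape2"]] %||% 5,
                     label = p[["label"]] %||% "")
  })
  simulation_scenario(layout, pops, depth = depth, seed = seed,
                      correlation_length = clen,
                      label = cfg[["label"]] %||% "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
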