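#' Binned genomic tracks
#'
#' Three track classes share the bin lattice of a [genome_layout()]:
#' `coverage_track` (non-negative per-bin read counts or normalized counts),
#' `timing_profile` (per-bin replication-timing quantile in \[0,1\], 0 =
#' earliest-replicating), and `ratio_track` (per-bin log2 query/reference
#' ratio with a validity mask).
#'
#' @param layout a `genome_layout` with bin size set.
#' @param values numeric vector, one value per bin in layout order.
#' @param label free-text sample label.
#' @return the corresponding track object.
#' @name tracks
NULL

#' @rdname tracks
#' @export
coverage_track <- function(layout, values, label = "") {
  stopifnot(inherits(layout, "genome_layout"))
  values <- as.numeric(values)
  if (length(values) != n_bins(layout)) stop("value count != bin count", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("coverage values must be finite and >= 0", call. = FALSE)
  }
  structure(list(layout = layout, values = values, label = label,
                 total = sum(values)),
            class = "coverage_track")
}

#' @rdname tracks
#' @export
timing_profile <- function(layout, values) {
  stopifnot(inherits(layout, "genome_layout"))
  values <- as.numeric(values)
  if (length(values) != n_bins(layout)) stop("value count != bin count", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("timing quantiles must lie in [0, 1]", call. = FALSE)
  }
  structure(list(layout = layout, values = values), class = "timing_profile")
}

#' @rdname tracks
#' @param mask logical vector, `TRUE` marking invalid bins; masked bins carry
#'   `NA` values.
#' @export
ratio_track <- function(layout, values, mask = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  values <- as.numeric(values)
  if (length(values) != n_bins(layout)) stop("value count != bin count", call. = FALSE)
  if (is.null(mask)) mask <- !is.finite(values)
  mask <- as.logical(mask) | !is.finite(values)
  values[mask] <- NA_real_
  if (any(!is.finite(values[!mask]))) stop("unmasked values must be finite", call. = FALSE)
  structure(list(layout = layout, values = values, mask = mask,
                 n_masked = sum(mask)),
            class = "ratio_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> '%s': %d bins, total = %.6g\n",
              x$label, n_bins(x$layout), x$total))
  invisible(x)
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %d bins, %d masked, sd(unmasked) = %.4g\n",
              n_bins(x$layout), x$n_masked, stats::sd(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.timing_profile <- function(x, ...) {
  cat(sprintf("<timing_profile> %d bins, range [%.3f, %.3f]\n",
              n_bins(x$layout), min(x$values), max(x$values)))
  invisible(x)
}

#' Read a bedGraph file onto a layout's bin lattice
#'
#' Each record's value is apportioned to the bins it overlaps,
#' proportionally to overlap length; bins with no record are 0. Records may
#' be unsorted but must not overlap each other, and must lie within the
#' layout's chromosomes.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param layout a `genome_layout` with bin size set.
#' @param label sample label for the returned track.
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, layout, label = basename(path)) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  track_from_granges(gr, layout, label = label, what = path)
}

track_from_granges <- function(gr, layout, label = "", what = "input") {
  chroms <- layout$chromosomes
  seqn <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(seqn), chroms$name)
  if (length(unknown)) {
    stop(what, ": record on unknown chromosome: ", unknown[1L], call. = FALSE)
  }
  lens <- stats::setNames(chroms$length, chroms$name)
  if (any(BiocGenerics::end(gr) > lens[seqn])) {
    stop(what, ": record beyond chromosome end", call. = FALSE)
  }
  self <- GenomicRanges::findOverlaps(gr, gr)
  if (length(self) > length(gr)) {
    stop(what, ": overlapping bedGraph records", call. = FALSE)
  }
  bins <- layout_granges(layout)
  hits <- GenomicRanges::findOverlaps(gr, bins)
  ov <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                            bins[S4Vectors::subjectHits(hits)])
  frac <- BiocGenerics::width(ov) / BiocGenerics::width(gr[S4Vectors::queryHits(hits)])
  contrib <- gr$score[S4Vectors::queryHits(hits)] * frac
  values <- numeric(n_bins(layout))
  agg <- rowsum(contrib, group = S4Vectors::subjectHits(hits))
  values[as.integer(rownames(agg))] <- agg[, 1L]
  coverage_track(layout, values, label = label)
}

#' Count aligned fragments per bin from a BAM file
#'
#' Each retained alignment is counted once, in the bin containing the
#' midpoint of its reference span. Unmapped, secondary and supplementary
#' records are ignored; with `dedupe = TRUE` (the default) records carrying
#' the duplicate flag are ignored as well — duplicate marking itself is an
#' upstream concern.
#'
#' @param path coordinate-sorted, indexed BAM file.
#' @param layout a `genome_layout` with bin size set.
#' @param dedupe drop duplicate-flagged records.
#' @param label sample label.
#' @return a `coverage_track` of fragment counts.
#' @export
bin_alignments <- function(path, layout, dedupe = TRUE, label = basename(path)) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  idx <- paste0(path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("missing BAM index for ", path, call. = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedupe) FALSE else NA
  )
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag)
  )
  values <- numeric(n_bins(layout))
  if (length(aln) > 0L) {
    seqn <- as.character(GenomeInfoDb::seqnames(aln))
    unknown <- setdiff(unique(seqn), layout$chromosomes$name)
    if (length(unknown)) stop("alignment on unknown chromosome: ", unknown[1L], call. = FALSE)
    # midpoint of the reference span, 0-based
    mid <- floor((BiocGenerics::start(aln) - 1 + BiocGenerics::end(aln) - 1) / 2)
    k <- pmin(floor(mid / layout$bin_size), ceiling(lens_of(layout)[seqn] / layout$bin_size) - 1)
    offset <- chrom_bin_offsets(layout)
    idxs <- offset[seqn] + k + 1
    tab <- table(idxs)
    values[as.integer(names(tab))] <- as.numeric(tab)
  }
  coverage_track(layout, values, label = label)
}

lens_of <- function(layout) stats::setNames(layout$chromosomes$length, layout$chromosomes$name)

chrom_bin_offsets <- function(layout) {
  nb <- bins_per_chrom(layout)
  stats::setNames(cumsum(c(0L, nb[-length(nb)])), layout$chromosomes$name)
}

#' Scale a coverage track to a target total
#'
#' Both samples of a comparison must carry the same total signal before
#' their ratio is meaningful; this rescales all bin values by
#' `target_total / total`.
#'
#' @param track a `coverage_track` with positive total.
#' @param target_total desired total signal (> 0).
#' @return a `coverage_track` whose total equals `target_total` (relative
#'   tolerance 1e-12).
#' @export
normalize_total <- function(track, target_total) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.finite(target_total) || target_total <= 0) {
    stop("target_total must be > 0", call. = FALSE)
  }
  if (track$total <= 0) stop("cannot normalize an all-zero track", call. = FALSE)
  coverage_track(track$layout, track$values * (target_total / track$total),
                 label = track$label)
}

#' Combine consecutive bins into larger bins
#'
#' Groups of `factor` consecutive bins within each chromosome are combined
#' by summation, so the track total is conserved exactly. Groups never span
#' chromosome boundaries; a trailing partial group is kept. Summed counts at
#' the coarser lattice correspond to coverage averaged over the wider bins
#' up to a constant, and taking ratios of summed counts is the lower-variance
#' convention for coarse-grained log2 ratio profiles.
#'
#' @param track a `coverage_track`.
#' @param factor positive integer number of bins to merge.
#' @return a `coverage_track` on a layout with `bin_size * factor`.
#' @export
rebin <- function(track, factor) {
  stopifnot(inherits(track, "coverage_track"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer", call. = FALSE)
  if (factor == 1L) return(track)
  layout <- track$layout
  nb <- bins_per_chrom(layout)
  grp_in_chrom <- unlist(lapply(nb, function(n) (seq_len(n) - 1L) %/% factor))
  chrom_id <- rep(seq_along(nb), nb)
  grp <- chrom_id * 10^ceiling(log10(max(grp_in_chrom) + 2)) + grp_in_chrom
  out_vals <- rowsum(track$values, group = grp, reorder = TRUE)[, 1L]
  new_layout <- set_bin_size(layout, layout$bin_size * factor)
  stopifnot(length(out_vals) == n_bins(new_layout))
  coverage_track(new_layout, unname(out_vals), label = track$label)
}

#' Per-bin log2 query/reference ratio
#'
#' Computes `log2(query / reference)` per bin. Bins where the reference is
#' below `min_ref` or the query is zero are masked rather than propagated as
#' infinities; pseudocounts are deliberately not used because they bias log
#' ratios at low depth. Both tracks must be on the same layout and should be
#' normalized to the same total (see [normalize_total()]).
#'
#' @param query,reference `coverage_track`s on the same layout.
#' @param min_ref minimum reference value for a bin to be used; the default
#'   is 25% of the genome-wide mean per-bin reference value.
#' @return a `ratio_track`; its `n_masked` element reports how many bins
#'   were excluded.
#' @export
log2_ratio <- function(query, reference, min_ref = NULL) {
  stopifnot(inherits(query, "coverage_track"), inherits(reference, "coverage_track"))
  if (!same_layout(query$layout, reference$layout)) {
    stop("query and reference are on different layouts", call. = FALSE)
  }
  if (is.null(min_ref)) min_ref <- 0.25 * mean(reference$values)
  if (!is.finite(min_ref) || min_ref <= 0) stop("min_ref must be > 0", call. = FALSE)
  mask <- reference$values < min_ref | query$values == 0
  vals <- ifelse(mask, NA_real_, log2(query$values / reference$values))
  ratio_track(query$layout, vals, mask = mask)
}

#' Interval mask sets
#'
#' A `mask_set` is a list of (chromosome, start, end) intervals in 0-based
#' half-open coordinates, used to exclude regions (e.g. centromeres) from a
#' ratio track.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return a `mask_set`.
#' @export
mask_set <- function(intervals) {
  stopifnot(is.data.frame(intervals), all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    stop("mask intervals must satisfy start < end", call. = FALSE)
  }
  structure(list(intervals = intervals[c("chrom", "start", "end")]), class = "mask_set")
}

#' @rdname mask_set
#' @param path BED3 file of intervals to mask.
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mask_set(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1L,
                      end = BiocGenerics::end(gr)))
}

#' Mask all bins overlapping a set of intervals
#'
#' @param track a `ratio_track`.
#' @param mask a `mask_set`.
#' @return the track with overlapping bins additionally masked.
#' @export
apply_mask <- function(track, mask) {
  stopifnot(inherits(track, "ratio_track"), inherits(mask, "mask_set"))
  iv <- mask$intervals
  if (nrow(iv) == 0L) return(track)
  lens <- lens_of(track$layout)
  unknown <- setdiff(unique(iv$chrom), names(lens))
  if (length(unknown)) stop("mask interval on unknown chromosome: ", unknown[1L], call. = FALSE)
  if (any(iv$start < 0) || any(iv$end > lens[iv$chrom])) {
    stop("mask interval outside chromosome bounds", call. = FALSE)
  }
  mgr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  hits <- GenomicRanges::findOverlaps(layout_granges(track$layout), mgr)
  newmask <- track$mask
  newmask[unique(S4Vectors::queryHits(hits))] <- TRUE
  ratio_track(track$layout, ifelse(newmask, NA_real_, track$values), mask = newmask)
}

#' Write a track as bedGraph
#'
#' One record per bin; masked bins of ratio tracks are omitted. Coverage
#' tracks written with integral counts round-trip exactly through
#' [read_bedgraph()].
#'
#' @param track a `coverage_track` or `ratio_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track") || inherits(track, "ratio_track"))
  if (n_bins(track$layout) == 0L) stop("cannot write a track on an empty layout", call. = FALSE)
  keep <- if (inherits(track, "ratio_track")) !track$mask else rep(TRUE, n_bins(track$layout))
  gr <- layout_granges(track$layout)[keep]
  gr$score <- track$values[keep]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
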