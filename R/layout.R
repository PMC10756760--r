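#' Genome layout: chromosomes plus a fixed bin lattice
#'
#' A `genome_layout` holds an ordered set of chromosomes with their lengths
#' and (optionally) a bin size. All tracks in the package live on the bin
#' lattice implied by a layout: each chromosome is cut into
#' `ceiling(length / bin_size)` consecutive bins; the final bin may be
#' partial and carries its true width. Coordinates are 0-based, half-open
#' throughout (bedGraph convention).
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length` (positive integer base pairs), in the desired order.
#' @param bin_size bin width in base pairs, or `NA` to leave the lattice
#'   undefined (as after [read_chrom_sizes()] without a bin size).
#' @return an object of class `genome_layout` with elements `chromosomes`,
#'   `bin_size`, and (when `bin_size` is set) a `bins` data.frame with
#'   columns `chrom`, `start`, `end`, `width`.
#' @examples
#' genome_layout(data.frame(name = "Chr1", length = 25000), bin_size = 10000)
#' @export
genome_layout <- function(chromosomes, bin_size = NA) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  name <- as.character(chromosomes$name)
  len <- as.numeric(chromosomes$length)
  if (anyDuplicated(name)) {
    stop("duplicate chromosome name: ", name[duplicated(name)][1L], call. = FALSE)
  }
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  obj <- structure(
    list(chromosomes = data.frame(name = name, length = len),
         bin_size = NA_real_, bins = NULL),
    class = "genome_layout"
  )
  if (!is.na(bin_size)) obj <- set_bin_size(obj, bin_size)
  obj
}

#' Set or change the bin size of a layout
#'
#' @param layout a `genome_layout`.
#' @param bin_size bin width in base pairs (> 0).
#' @return the layout with its bin lattice (re)computed.
#' @export
set_bin_size <- function(layout, bin_size) {
  stopifnot(inherits(layout, "genome_layout"))
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be > 0", call. = FALSE)
  per <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    data.frame(chrom = layout$chromosomes$name[i], start = start, end = end,
               width = end - start)
  })
  layout$bin_size <- bin_size
  layout$bins <- if (length(per)) do.call(rbind, per) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               width = numeric(0))
  rownames(layout$bins) <- NULL
  layout
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-delimited columns: chromosome name, length in base pairs.
#' Chromosome order follows the file.
#'
#' @param path path to the chrom.sizes file.
#' @param bin_size optional bin width to set on the returned layout.
#' @return a `genome_layout`.
#' @export
read_chrom_sizes <- function(path, bin_size = NA) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) stop("malformed chrom.sizes line ", bad[1L], ": ", lines[bad[1L]], call. = FALSE)
  name <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(!is.finite(len) | len <= 0)
  if (length(bad)) stop("non-positive or unparsable length at line ", bad[1L], ": ", lines[bad[1L]], call. = FALSE)
  if (anyDuplicated(name)) {
    stop("duplicate chromosome name at line ", which(duplicated(name))[1L], call. = FALSE)
  }
  genome_layout(data.frame(name = name, length = len), bin_size = bin_size)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %s bp total",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ",")))
  if (!is.na(x$bin_size)) {
    cat(sprintf("; bin_size = %s bp, %d bins", format(x$bin_size, big.mark = ","), n_bins(x)))
  } else {
    cat("; bin lattice unset")
  }
  cat("\n")
  invisible(x)
}

#' Number of bins in a layout
#' @param layout a `genome_layout` with bin size set.
#' @return integer bin count.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.na(layout$bin_size)) stop("layout has no bin size", call. = FALSE)
  nrow(layout$bins)
}

#' Bins of a layout as a GRanges (1-based closed intervals)
#' @param layout a `genome_layout` with bin size set.
#' @return a `GRanges`, one range per bin, in layout order.
#' @export
layout_granges <- function(layout) {
  b <- layout$bins
  if (is.null(b)) stop("layout has no bin size", call. = FALSE)
  GenomicRanges::GRanges(
    seqnames = factor(b$chrom, levels = layout$chromosomes$name),
    ranges = IRanges::IRanges(start = b$start + 1L, end = b$end),
    seqlengths = stats::setNames(layout$chromosomes$length, layout$chromosomes$name)
  )
}

same_layout <- function(a, b) {
  identical(a$chromosomes$name, b$chromosomes$name) &&
    isTRUE(all.equal(a$chromosomes$length, b$chromosomes$length)) &&
    isTRUE(all.equal(a$bin_size, b$bin_size))
}

# per-chromosome bin counts, in layout order
bins_per_chrom <- function(layout) {
  tab <- table(factor(layout$bins$chrom, levels = layout$chromosomes$name))
  as.integer(tab)
}

#' Convenience synthetic genome layout
#'
#' Equal-length chromosomes named Chr1..Chrn; the default (5 x 2 Mb at 10-kb
#' bins, 1000 bins) matches the package's standard simulation conditions.
#'
#' @param genome_size total genome size in bp.
#' @param n_chrom number of chromosomes.
#' @param bin_size bin width in bp.
#' @return a `genome_layout`.
#' @export
default_layout <- function(genome_size = 1e7, n_chrom = 5, bin_size = 1e4) {
  len <- genome_size / n_chrom
  genome_layout(data.frame(name = paste0("Chr", seq_len(n_chrom)), length = len),
                bin_size = bin_size)
}
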