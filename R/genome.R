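#' Describe a genome as a set of named chromosomes
#'
#' A genome layout is the minimal description of the physical coordinate
#' system used throughout the package: unique chromosome names and their
#' lengths in base pairs.  All simulated data, interval operations and
#' recombination tracks refer to a layout.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Integer/numeric vector of chromosome lengths (bp),
#'   parallel to `chrom_names`; all must be positive.
#' @return An object of class `genome_layout`: a named numeric vector of
#'   lengths.
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(5e6, 4e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stopf("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stopf("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stopf("all chromosome lengths must be positive")
  structure(setNames(chrom_lengths, chrom_names), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Convert a genome layout to a Seqinfo object
#'
#' @param layout A [genome_layout()].
#' @return A [GenomeInfoDb::Seqinfo] usable to bound `GRanges`.
#' @export
as_seqinfo <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  GenomeInfoDb::Seqinfo(seqnames = names(layout), seqlengths = as.integer(layout))
}

#' Tile a genome layout into fixed-size bins
#'
#' @param layout A [genome_layout()].
#' @param binsize Bin width in bp (last bin per chromosome may be shorter).
#' @return A `GRanges` of non-overlapping bins covering each chromosome.
#' @export
layout_bins <- function(layout, binsize = 1e5) {
  stopifnot(inherits(layout, "genome_layout"), binsize >= 1)
  grl <- GenomicRanges::tileGenome(as_seqinfo(layout), tilewidth = binsize,
                                   cut.last.tile.in.chrom = TRUE)
  grl
}
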