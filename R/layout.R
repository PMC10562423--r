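#' Genome layout: chromosomes and a fixed bin size
#'
#' A layout ties chromosome names and lengths to a binning resolution. All
#' binned containers in the package (contact matrices, signal tracks) carry a
#' layout so that bin index `floor(start / bin_size)` is unambiguous.
#' Coordinates are 0-based half-open throughout.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (> 0).
#' @return an object of class `genome_layout`.
#' @examples
#' genome_layout(c(chrS = 2e7), bin_size = 1e4)
#' @export
genome_layout <- function(chrom_lengths, bin_size) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = as.numeric(bin_size)),
    class = "genome_layout"
  )
}

#' Number of bins for a chromosome under a layout
#' @param layout a `genome_layout`.
#' @param chrom chromosome name.
#' @return integer number of bins.
#' @export
n_bins <- function(layout, chrom) {
  stopifnot(inherits(layout, "genome_layout"))
  len <- layout$chrom_lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  as.integer(ceiling(len / layout$bin_size))
}

#' Map 0-based coordinates to 0-based bin indices
#' @param pos 0-based positions in bp.
#' @param bin_size bin width in bp.
#' @return integer bin indices.
#' @export
coord_to_bin <- function(pos, bin_size) as.integer(floor(pos / bin_size))

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_lengths), "chromosome(s), bin size",
      x$bin_size, "bp\n")
  for (ch in names(x$chrom_lengths))
    cat("  ", ch, ": ", x$chrom_lengths[[ch]], " bp (",
        ceiling(x$chrom_lengths[[ch]] / x$bin_size), " bins)\n", sep = "")
  invisible(x)
}
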