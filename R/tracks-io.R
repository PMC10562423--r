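#' Read a BED file as a peak set
#'
#' Accepts BED3+; column 4 becomes `name`, 5 `score`, 6 `strand` when
#' present. Returns a `GRanges` (0-based half-open input converted to the
#' 1-based closed convention `GRanges` uses internally; all package code goes
#' through this reader and its writer so the on-disk convention is uniform).
#'
#' @param path BED file path.
#' @return a `GenomicRanges::GRanges`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs >= 3 columns: ", path)
  bad <- which(df[[2]] >= df[[3]])
  if (length(bad)) stop("BED start >= end at line ", bad[1], " of ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (ncol(df) >= 6) df[[6]] else "*")
  if (ncol(df) >= 4) gr$name <- df[[4]]
  if (ncol(df) >= 5) gr$score <- df[[5]]
  gr
}

#' Write a peak set as BED
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) {
    if (is.null(df$name)) df$name <- "."
    df$score <- gr$score
  }
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-bin signal track
#'
#' @param values numeric per-bin values (length = number of bins).
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param library_size mapped-read count backing the track (for RPM scaling).
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(values, chrom, bin_size, library_size = NA_real_) {
  stopifnot(is.numeric(values))
  structure(list(values = as.numeric(values), chrom = chrom,
                 bin_size = bin_size, n_bins = length(values),
                 library_size = library_size),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track: ", x$chrom, ", ", x$n_bins, " bins x ", x$bin_size,
      " bp, total = ", format(sum(x$values)), "\n", sep = "")
  invisible(x)
}

#' Read a bedGraph and rebin onto a layout
#'
#' Each interval's value contributes to overlapping bins in proportion to the
#' overlapped length; uncovered bases count as zero, so a bin's value is the
#' per-base mean over the bin. Overlapping input intervals are rejected
#' because the signal would be ambiguous.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param layout a `genome_layout`.
#' @param chrom chromosome to extract.
#' @return a `signal_track` on the layout's bins.
#' @export
read_bedgraph <- function(path, layout, chrom) {
  nb <- n_bins(layout, chrom)
  bw <- layout$bin_size
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: ", path)
  df <- df[df[[1]] == chrom, , drop = FALSE]
  vals <- numeric(nb)
  if (nrow(df)) {
    ord <- order(df[[2]])
    df <- df[ord, , drop = FALSE]
    if (any(df[[2]][-1] < df[[3]][-nrow(df)]))
      stop("overlapping bedGraph intervals in ", path)
    vals <- rebin_intervals(df[[2]], df[[3]], df[[4]], nb, bw)
  }
  signal_track(vals, chrom, bw)
}

## Length-weighted rebinning of disjoint intervals onto fixed bins.
rebin_intervals <- function(start, end, value, nb, bw) {
  vals <- numeric(nb)
  for (k in seq_along(start)) {
    s <- start[k]; e <- min(end[k], nb * bw)
    if (e <= s) next
    b0 <- coord_to_bin(s, bw)
    b1 <- coord_to_bin(e - 1, bw)
    bins <- b0:b1
    lo <- pmax(s, bins * bw)
    hi <- pmin(e, (bins + 1) * bw)
    vals[bins + 1L] <- vals[bins + 1L] + value[k] * (hi - lo) / bw
  }
  vals
}

#' Write a per-bin track as bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  nz <- which(track$values != 0)
  df <- data.frame(chrom = rep(track$chrom, length(nz)),
                   start = (nz - 1) * track$bin_size,
                   end = nz * track$bin_size,
                   value = track$values[nz])
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
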