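#' Loop set: ordered anchor pairs
#'
#' A `loop_set` is a data.frame with columns `chrom`, `start1`, `end1`,
#' `start2`, `end2` (0-based half-open) plus any extra columns. Anchors are
#' canonicalized so that `anchor1` lies 5' of `anchor2` on the chromosome.
#'
#' @param chrom chromosome name per loop.
#' @param start1,end1,start2,end2 anchor coordinates (0-based half-open).
#' @param ... further per-loop columns (e.g. `stage`, `name`).
#' @return a data.frame of class `loop_set`.
#' @export
loop_set <- function(chrom, start1, end1, start2, end2, ...) {
  df <- data.frame(chrom = chrom, start1 = start1, end1 = end1,
                   start2 = start2, end2 = end2, ...,
                   stringsAsFactors = FALSE)
  bad <- which(df$start1 >= df$end1 | df$start2 >= df$end2)
  if (length(bad)) stop("anchor with start >= end at row ", bad[1])
  swap <- df$start1 > df$start2
  if (any(swap)) {
    s1 <- df$start1[swap]; e1 <- df$end1[swap]
    df$start1[swap] <- df$start2[swap]; df$end1[swap] <- df$end2[swap]
    df$start2[swap] <- s1; df$end2[swap] <- e1
  }
  class(df) <- c("loop_set", "data.frame")
  df
}

#' Read loops from a BEDPE file
#'
#' Expects at least six columns (`chrom1 start1 end1 chrom2 start2 end2`);
#' remaining columns are kept as `extra1`, `extra2`, ... Anchors are stored
#' in canonical 5' -> 3' order. Inter-chromosomal rows are dropped with a
#' warning (the pipeline is cis-only).
#'
#' @param path BEDPE file path.
#' @return a `loop_set`.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE needs >= 6 columns: ", path)
  bad <- which(df[[2]] >= df[[3]] | df[[5]] >= df[[6]])
  if (length(bad))
    stop("malformed BEDPE row (start >= end) at line ", bad[1], " of ", path)
  trans <- df[[1]] != df[[4]]
  if (any(trans)) {
    warning(sum(trans), " inter-chromosomal row(s) dropped from ", path)
    df <- df[!trans, , drop = FALSE]
  }
  extra <- if (ncol(df) > 6) {
    e <- df[, -(1:6), drop = FALSE]
    names(e) <- paste0("extra", seq_len(ncol(e)))
    e
  } else NULL
  out <- loop_set(df[[1]], df[[2]], df[[3]], df[[5]], df[[6]])
  ## loop_set() re-sorts anchors within row but keeps row order
  if (!is.null(extra)) out <- cbind(out, extra)
  class(out) <- c("loop_set", "data.frame")
  out
}

#' Write loops to a BEDPE file
#' @param loops a `loop_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(loops$chrom, loops$start1, loops$end1,
                   loops$chrom, loops$start2, loops$end2)
  extra <- setdiff(names(loops), c("chrom", "start1", "end1", "start2", "end2"))
  for (cn in extra) df[[cn]] <- loops[[cn]]
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Anchor midpoints (bp) and bin indices for a loop_set.
loop_anchor_mids <- function(loops) {
  data.frame(mid1 = (loops$start1 + loops$end1) / 2,
             mid2 = (loops$start2 + loops$end2) / 2)
}

loop_anchor_bins <- function(loops, bin_size) {
  m <- loop_anchor_mids(loops)
  data.frame(bin1 = coord_to_bin(m$mid1, bin_size),
             bin2 = coord_to_bin(m$mid2, bin_size))
}
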