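#' Sparse symmetric binned contact matrix
#'
#' Stores one chromosome's intra-chromosomal contacts in canonical
#' upper-triangle triplet form (`bin1 <= bin2`, 0-based bins). Entries given
#' below the diagonal are mirrored onto the upper triangle and duplicates are
#' summed, so construction is idempotent. Raw matrices must have non-negative
#' integer counts; distance-normalized matrices are dense-backed and may hold
#' negative values.
#'
#' @param bin1,bin2 0-based bin indices.
#' @param value contact values.
#' @param n_bins number of bins on this chromosome.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param norm_state one of `"raw"`, `"subsampled"`, `"KR"`, `"VCsqrt"`,
#'   `"distance_normalized"`.
#' @param masked optional logical vector (length `n_bins`) of bins excluded
#'   from balancing/expected computation.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bin1, bin2, value, n_bins, chrom = "chr1",
                           bin_size = 1, norm_state = "raw", masked = NULL) {
  norm_state <- match.arg(norm_state,
    c("raw", "subsampled", "KR", "VCsqrt", "distance_normalized"))
  n_bins <- as.integer(n_bins)
  stopifnot(length(bin1) == length(bin2), length(bin2) == length(value),
            n_bins >= 1)
  bin1 <- as.integer(bin1); bin2 <- as.integer(bin2)
  value <- as.numeric(value)
  bad <- which(bin1 < 0L | bin2 < 0L | bin1 >= n_bins | bin2 >= n_bins)
  if (length(bad))
    stop("bin index outside layout (n_bins = ", n_bins, ") at entry ", bad[1])
  if (norm_state %in% c("raw", "subsampled")) {
    if (any(value < 0))
      stop("negative raw count at entry ", which(value < 0)[1])
    if (any(value != round(value)))
      stop("raw counts must be integers (entry ",
           which(value != round(value))[1], ")")
  }
  ## mirror below-diagonal entries, then merge duplicates by summation
  swap <- bin1 > bin2
  if (any(swap)) {
    tmp <- bin1[swap]; bin1[swap] <- bin2[swap]; bin2[swap] <- tmp
  }
  if (length(bin1)) {
    key <- bin1 * as.numeric(n_bins) + bin2
    if (anyDuplicated(key)) {
      agg <- rowsum(value, key)
      key <- as.numeric(rownames(agg))
      value <- as.numeric(agg[, 1])
      bin1 <- as.integer(key %/% n_bins)
      bin2 <- as.integer(key %% n_bins)
    }
    ord <- order(bin1, bin2)
    bin1 <- bin1[ord]; bin2 <- bin2[ord]; value <- value[ord]
  }
  keep <- value != 0
  structure(
    list(bin1 = bin1[keep], bin2 = bin2[keep], value = value[keep],
         n_bins = n_bins, chrom = chrom, bin_size = bin_size,
         norm_state = norm_state,
         total_contacts = if (norm_state %in% c("raw", "subsampled"))
           sum(value[keep]) else NA_real_,
         masked = masked, dense = NULL),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix: ", x$chrom, ", ", x$n_bins, " bins x ", x$bin_size,
      " bp, state = ", x$norm_state, "\n", sep = "")
  cat("  entries: ", length(x$value),
      if (!is.na(x$total_contacts))
        paste0(", total contacts: ", format(x$total_contacts)), "\n", sep = "")
  invisible(x)
}

#' Dense symmetric matrix view of a contact matrix
#'
#' @param cm a `contact_matrix`.
#' @return an `n_bins x n_bins` symmetric numeric matrix. For dense-backed
#'   (distance-normalized) objects the stored matrix is returned directly.
#' @export
cm_dense <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (!is.null(cm$dense)) return(cm$dense)
  n <- cm$n_bins
  m <- matrix(0, n, n)
  if (length(cm$value)) {
    m[cbind(cm$bin1 + 1L, cm$bin2 + 1L)] <- cm$value
    m[cbind(cm$bin2 + 1L, cm$bin1 + 1L)] <- cm$value
  }
  m
}

## Build a contact_matrix around a dense symmetric matrix (normalized states).
cm_from_dense <- function(dense, template, norm_state, masked = NULL) {
  out <- template
  out$dense <- dense
  out$bin1 <- integer(0); out$bin2 <- integer(0); out$value <- numeric(0)
  out$norm_state <- norm_state
  out$total_contacts <- NA_real_
  if (!is.null(masked)) out$masked <- masked
  out
}

#' Pool raw contact matrices (e.g. replicates) by summing counts
#'
#' @param matrices list of raw/subsampled `contact_matrix` objects on the
#'   same layout.
#' @return a single pooled `contact_matrix` in `raw` state.
#' @export
pool_replicates <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "contact_matrix")))
  tpl <- matrices[[1]]
  contact_matrix(unlist(lapply(matrices, `[[`, "bin1")),
                 unlist(lapply(matrices, `[[`, "bin2")),
                 unlist(lapply(matrices, `[[`, "value")),
                 tpl$n_bins, tpl$chrom, tpl$bin_size)
}

#' Canonical triplet entries of a contact matrix
#'
#' @param cm a `contact_matrix`.
#' @return data.frame with columns `bin1`, `bin2` (0-based, `bin1 <= bin2`)
#'   and `value`; zero entries omitted.
#' @export
cm_entries <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(cm$dense))
    return(data.frame(bin1 = cm$bin1, bin2 = cm$bin2, value = cm$value))
  idx <- which(upper.tri(cm$dense, diag = TRUE) & cm$dense != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
             value = cm$dense[idx])
}

#' Read a bin-triplet contact file
#'
#' Lines are whitespace-separated `bin1 bin2 value` with 0-based bin indices.
#' Lower-triangle entries are mirrored and merged; `total_contacts` is
#' populated for raw data.
#'
#' @param path file path.
#' @param layout a `genome_layout`.
#' @param chrom chromosome the file belongs to.
#' @return a `contact_matrix` in `raw` state.
#' @export
read_contacts <- function(path, layout, chrom) {
  nb <- n_bins(layout, chrom)
  if (file.size(path) == 0)
    return(contact_matrix(integer(0), integer(0), numeric(0), nb, chrom,
                          layout$bin_size))
  df <- utils::read.table(path, header = FALSE,
                          colClasses = c("numeric", "numeric", "numeric"))
  if (ncol(df) < 3) stop("triplet file needs 3 columns: ", path)
  bad <- which(df[[1]] < 0 | df[[2]] < 0 | df[[1]] >= nb | df[[2]] >= nb)
  if (length(bad))
    stop("bin outside layout at line ", bad[1], " of ", path, ": '",
         paste(unlist(df[bad[1], ]), collapse = " "), "'")
  if (any(df[[3]] < 0))
    stop("negative raw count at line ", which(df[[3]] < 0)[1], " of ", path)
  contact_matrix(df[[1]], df[[2]], df[[3]], nb, chrom, layout$bin_size)
}

#' Write a contact matrix as bin triplets
#' @param cm a `contact_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path) {
  ent <- cm_entries(cm)
  utils::write.table(ent, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
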