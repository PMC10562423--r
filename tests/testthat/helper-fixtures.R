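## Shared fixture builders (all fixtures are generated in code).

## Random raw contact matrix with given bin count and fill density.
random_cm <- function(n, density = 0.3, max_count = 20, seed = NULL,
                      chrom = "chrT", bin_size = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  ut <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  ut <- ut[ut$i <= ut$j, ]
  keep <- runif(nrow(ut)) < density
  ut <- ut[keep, , drop = FALSE]
  contact_matrix(ut$i, ut$j, sample.int(max_count, nrow(ut), replace = TRUE),
                 n, chrom, bin_size)
}

## Strictly positive symmetric dense matrix (for balancing tests).
random_positive_dense <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(runif(n * n, 0.5, 5), n, n)
  a <- (a + t(a)) / 2
  a
}

dense_to_cm <- function(a, norm_state = "KR", bin_size = 1e4) {
  n <- nrow(a)
  idx <- which(upper.tri(a, diag = TRUE), arr.ind = TRUE)
  ## construct under a normalized state (no integer check), then re-tag
  cm <- contact_matrix(idx[, 1] - 1L, idx[, 2] - 1L, a[idx], n, "chrT",
                       bin_size, norm_state = "KR")
  cm$norm_state <- norm_state
  if (norm_state %in% c("raw", "subsampled"))
    cm$total_contacts <- sum(a[idx])
  cm
}

## Independent IPF (iterative proportional fitting) oracle for symmetric
## doubly-balanced scaling: returns the balanced matrix.
ipf_balance <- function(a, tol = 1e-12, max_iter = 1e5) {
  x <- rep(1, nrow(a))
  for (k in seq_len(max_iter)) {
    rs <- x * as.vector(a %*% x)
    if ((max(rs) - min(rs)) / mean(rs) < tol) break
    x <- x / sqrt(rs / mean(rs))
  }
  x <- x / sqrt(mean(x * (a %*% x)))
  a * outer(x, x)
}

## Brute-force per-diagonal mean (expected-model oracle).
brute_expected <- function(dense, masked = NULL) {
  n <- nrow(dense)
  um <- if (is.null(masked)) rep(TRUE, n) else !masked
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    ok <- um[i] & um[i + d]
    if (!any(ok)) return(NA_real_)
    mean(dense[cbind(i[ok], i[ok] + d)])
  }, 0)
}

## Simple loop_set around given pixel bins.
pixel_loops <- function(bin1, bin2, bin_size = 1e4, chrom = "chrT") {
  loop_set(chrom = rep(chrom, length(bin1)),
           start1 = bin1 * bin_size, end1 = (bin1 + 1) * bin_size,
           start2 = bin2 * bin_size, end2 = (bin2 + 1) * bin_size)
}

## GRanges helper.
gr <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         strand = strand)
}

## Brute-force conditional two-sided exact NB p-value by enumeration.
brute_nb_p <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  x <- 0:t
  if (phi == 0) {
    w <- dbinom(x, t, na / (na + nb))
  } else {
    ra <- na / phi; rb <- nb / phi
    logw <- lgamma(x + ra) - lgamma(x + 1) - lgamma(ra) +
      lgamma(t - x + rb) - lgamma(t - x + 1) - lgamma(rb)
    w <- exp(logw - max(logw))
    w <- w / sum(w)
  }
  min(1, 2 * min(sum(w[x <= sa]), sum(w[x >= sa])))
}
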