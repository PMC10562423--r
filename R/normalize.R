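#' Subsample contact libraries to a common depth
#'
#' Randomly picks contact events without replacement from each matrix so
#' that every library ends up with the total of the smallest one — the
#' standard depth-matching step before comparing contact maps.
#'
#' @param matrices list of raw `contact_matrix` objects.
#' @param seed optional integer seed; the draw is reproducible given it.
#' @param target target total (default: minimum of the input totals).
#' @return list of `contact_matrix` objects in `subsampled` state.
#' @export
subsample_contacts <- function(matrices, seed = NULL, target = NULL) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "contact_matrix")))
  states <- vapply(matrices, function(m) m$norm_state, "")
  if (!all(states %in% c("raw", "subsampled")))
    stop("subsampling requires raw count matrices")
  totals <- vapply(matrices, function(m) m$total_contacts, 0)
  if (is.null(target)) target <- min(totals)
  if (any(totals < target))
    stop("matrix with total ", min(totals), " is below target ", target)
  if (!is.null(seed)) set.seed(seed)
  lapply(matrices, function(m) {
    if (m$total_contacts == target) {
      m$norm_state <- "subsampled"
      return(m)
    }
    counts <- as.integer(m$value)
    events <- rep.int(seq_along(counts), counts)
    keep <- sample.int(length(events), target)
    newv <- tabulate(events[keep], nbins = length(counts))
    contact_matrix(m$bin1, m$bin2, newv, m$n_bins, m$chrom, m$bin_size,
                   norm_state = "subsampled")
  })
}

#' Balance a contact matrix (KR or VCsqrt)
#'
#' KR finds a symmetric scaling vector `v` such that `v_i v_j raw(i,j)` has
#' equal row sums on all unmasked bins (Knight-Ruiz Newton iteration, with an
#' iterative-correction fallback for matrices on which the Newton scheme
#' stalls). VCsqrt divides each entry by the square root of the product of
#' its row and column marginals. Bins with zero marginal are masked.
#'
#' @param cm a raw or subsampled `contact_matrix`.
#' @param method `"KR"` or `"VCsqrt"`.
#' @param tol relative row-sum spread tolerance for KR.
#' @param max_iter maximum balancing iterations.
#' @return a `contact_matrix` in `KR` or `VCsqrt` state (dense-backed) with
#'   the mask recorded; KR results carry the scaling vector as attribute
#'   `"scaling"`.
#' @export
balance <- function(cm, method = c("KR", "VCsqrt"), tol = 1e-6,
                    max_iter = 3000) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "contact_matrix"))
  dense <- cm_dense(cm)
  marg <- rowSums(dense)
  masked <- marg == 0
  if (!is.null(cm$masked)) masked <- masked | cm$masked
  if (method == "VCsqrt") {
    out <- dense
    rs <- marg
    rs[masked] <- NA_real_
    denom <- sqrt(outer(rs, rs))
    out <- ifelse(denom > 0, dense / denom, 0)
    out[is.na(out)] <- 0
    return(cm_from_dense(out, cm, "VCsqrt", masked = masked))
  }
  A <- dense[!masked, !masked, drop = FALSE]
  v <- kr_scaling(A, tol = tol, max_iter = max_iter)
  if (is.null(v)) {
    v <- ice_scaling(A, tol = tol, max_iter = max_iter)
    if (is.null(v))
      stop("KR balancing failed to converge within ", max_iter,
           " iterations (ICE fallback also stalled); row-sum spread trace ",
           "available via options(loopshift.trace = TRUE)")
  }
  full_v <- numeric(cm$n_bins)
  full_v[!masked] <- v
  out <- dense * outer(full_v, full_v)
  res <- cm_from_dense(out, cm, "KR", masked = masked)
  attr(res, "scaling") <- full_v
  res
}

## Knight-Ruiz balancing: inner-outer Newton iteration with CG inner solves.
## Returns the scaling vector x (rows of diag(x) A diag(x) sum to 1), or NULL
## if the scheme does not reach tol within max_iter matrix-vector products.
kr_scaling <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  if (n == 0) return(numeric(0))
  if (any(rowSums(A) == 0)) return(NULL)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0
  while (rout > rt) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + k + 1
    if (mvp > max_iter) return(NULL)
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / max(res_norm, .Machine$double.eps))
    if (!all(is.finite(x))) return(NULL)
  }
  ## polish: row sums of diag(x) A diag(x) should be 1 within tol
  rs <- x * as.vector(A %*% x)
  if ((max(rs) - min(rs)) / mean(rs) > 10 * tol) return(NULL)
  x
}

## Iterative correction (IPF on the symmetric square-root scale): divide the
## scaling vector by sqrt(row sums) until the row sums agree.
ice_scaling <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    rs <- x * as.vector(A %*% x)
    spread <- (max(rs) - min(rs)) / mean(rs)
    if (spread <= tol) return(x / sqrt(mean(rs)))
    x <- x / sqrt(rs / mean(rs))
    if (!all(is.finite(x))) return(NULL)
  }
  NULL
}

#' Expected contact value per genomic distance
#'
#' The expected model holds, for each separation `d = |i - j|` in bins, the
#' mean contact value over all valid (unmasked) pixel positions at that
#' separation on the chromosome.
#'
#' @param cm a `contact_matrix` (any state).
#' @return an object of class `expected_model` with fields `values`
#'   (E(d) for d = 0..n_bins-1), `n_valid` and `chrom`.
#' @export
expected_by_distance <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  um <- rep(TRUE, n)
  if (!is.null(cm$masked)) um <- !cm$masked
  ## valid pixel positions per separation: pairs (i, i+d) with both unmasked
  n_valid <- vapply(0:(n - 1), function(d) {
    sum(um[seq_len(n - d)] & um[seq_len(n - d) + d])
  }, 0L)
  if (is.null(cm$dense)) {
    keep <- um[cm$bin1 + 1L] & um[cm$bin2 + 1L]
    d <- cm$bin2[keep] - cm$bin1[keep]
    sums <- numeric(n)
    if (length(d)) {
      agg <- rowsum(cm$value[keep], d)
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
  } else {
    sums <- vapply(0:(n - 1), function(d) {
      i <- seq_len(n - d)
      ok <- um[i] & um[i + d]
      sum(cm$dense[cbind(i[ok], i[ok] + d)])
    }, 0)
  }
  E <- ifelse(n_valid > 0, sums / n_valid, NA_real_)
  structure(list(values = E, n_valid = n_valid, chrom = cm$chrom,
                 bin_size = cm$bin_size),
            class = "expected_model")
}

#' Distance-normalize a contact matrix
#'
#' With `method = "residual"` (default) applies
#' `(observed - expected) / (expected + 1)` pixel-wise, where `expected` is
#' the mean contact value at the pixel's separation; residual values center
#' on zero and may be negative. With `method = "ratio"` computes the classic
#' observed-over-expected ratio `O / E(d)` (background centers on one; used
#' for APA stacks). The result is dense-backed: zero observed pixels get
#' `-E/(E+1)` (resp. 0), not a sparse hole.
#'
#' @param cm a `contact_matrix`.
#' @param expected an `expected_model`; computed from `cm` when missing.
#' @param method `"residual"` or `"ratio"`.
#' @return a `contact_matrix` in `distance_normalized` state.
#' @export
distance_normalize <- function(cm, expected = NULL,
                               method = c("residual", "ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(expected)) expected <- expected_by_distance(cm)
  n <- cm$n_bins
  E <- expected$values
  if (length(E) < n) stop("expected model does not cover all separations")
  dense <- cm_dense(cm)
  dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  Emat <- matrix(E[dmat + 1L], n, n)
  if (anyNA(Emat)) {
    present <- tabulate_separations(dense)
    if (any(present & is.na(E[seq_len(n)])))
      stop("expected model missing E(d) for a separation present in matrix")
    Emat[is.na(Emat)] <- 0
  }
  out <- if (method == "residual") {
    (dense - Emat) / (Emat + 1)
  } else {
    ifelse(Emat > 0, dense / Emat, 0)
  }
  um <- rep(TRUE, n)
  if (!is.null(cm$masked)) um <- !cm$masked
  out[!um, ] <- NA_real_
  out[, !um] <- NA_real_
  res <- cm_from_dense(out, cm, "distance_normalized")
  attr(res, "expected") <- expected
  res
}

tabulate_separations <- function(dense) {
  n <- nrow(dense)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    any(dense[cbind(i, i + d)] != 0)
  }, TRUE)
}

#' A/B compartment eigenvector
#'
#' Leading eigenvector of the Pearson correlation matrix of the
#' distance-normalized contact map, the standard compartment readout.
#' Bins with zero marginal or constant correlation-profile are masked.
#' When an orientation track is supplied, the sign is flipped so the
#' eigenvector correlates positively with it (e.g. an active-chromatin mark,
#' making positive = A compartment).
#'
#' @param cm a per-chromosome `contact_matrix` (typically 25-kb bins).
#' @param orientation_track optional `signal_track` on the same bins.
#' @return an object of class `compartment_call`: `values` (full-length,
#'   `NA` at masked bins), `masked` logical vector.
#' @export
compartment_eigenvector <- function(cm, orientation_track = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  if (cm$norm_state != "distance_normalized")
    cm <- distance_normalize(cm)
  dense <- cm_dense(cm)
  masked <- apply(dense, 1, function(r) all(is.na(r)) ||
                    stats::sd(r, na.rm = TRUE) == 0)
  masked[is.na(masked)] <- TRUE
  if (sum(!masked) < 2) {
    return(structure(list(values = rep(NA_real_, n), masked = masked,
                          chrom = cm$chrom, bin_size = cm$bin_size),
                     class = "compartment_call"))
  }
  sub <- dense[!masked, !masked, drop = FALSE]
  C <- suppressWarnings(stats::cor(sub))
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  if (!is.null(orientation_track)) {
    s <- sum(e1 * orientation_track$values[!masked])
    if (s < 0) e1 <- -e1
  } else if (e1[which.max(abs(e1))] < 0) {
    e1 <- -e1  # deterministic sign when no orientation track is given
  }
  values <- rep(NA_real_, n)
  values[!masked] <- e1
  structure(list(values = values, masked = masked, chrom = cm$chrom,
                 bin_size = cm$bin_size),
            class = "compartment_call")
}
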