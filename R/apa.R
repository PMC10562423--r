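#' Build an aggregate peak analysis (APA) stack
#'
#' Extracts, for every loop, the `(2*flank+1)` square pixel window of the
#' (normalized) contact map centered on the loop pixel — the bin pair holding
#' the two anchor midpoints — and aggregates per pixel across loops. With the
#' default flank of 10 bins at 10-kb resolution each window covers
#' 210 kb x 210 kb. Rows index the 5' (smaller-coordinate) anchor, columns
#' the 3' anchor; row/column indices increase with genomic coordinate, so
#' the window's lower-right corner lies away from the diagonal on both axes
#' and the top-right corner crosses over the loop.
#'
#' Loops whose window would cross the diagonal (`bin2 - bin1 <= 2*flank`) or
#' run off the chromosome are dropped and counted.
#'
#' @param cm a `contact_matrix`, typically O/E-style normalized.
#' @param loops a `loop_set` on the same chromosome.
#' @param flank window half-width in bins.
#' @param stat aggregate statistic across loops: `"median"` or `"mean"`.
#' @return an object of class `apa_stack`: `aggregate` (matrix), `windows`
#'   (loops x row x col array), `n_loops`, `n_dropped`, `flank`, `stat`.
#' @export
build_apa_stack <- function(cm, loops, flank = 10, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(cm, "contact_matrix"), inherits(loops, "loop_set"))
  dense <- cm_dense(cm)
  n <- cm$n_bins
  ab <- loop_anchor_bins(loops, cm$bin_size)
  keep <- ab$bin1 - flank >= 0 & ab$bin2 + flank <= n - 1 &
    (ab$bin2 - ab$bin1) > 2 * flank
  if (!any(keep)) stop("no loops retained for APA (all near diagonal/edge)")
  w <- 2 * flank + 1
  kept <- which(keep)
  windows <- array(NA_real_, dim = c(length(kept), w, w))
  off <- -flank:flank
  for (k in seq_along(kept)) {
    i <- ab$bin1[kept[k]] + 1L
    j <- ab$bin2[kept[k]] + 1L
    windows[k, , ] <- dense[i + off, j + off]
  }
  aggregate <- apply(windows, c(2, 3),
                     if (stat == "median") stats::median else mean,
                     na.rm = TRUE)
  structure(list(aggregate = aggregate, windows = windows,
                 n_loops = length(kept), n_dropped = sum(!keep),
                 flank = flank, stat = stat, kept = kept),
            class = "apa_stack")
}

#' @export
print.apa_stack <- function(x, ...) {
  cat("apa_stack: ", x$n_loops, " loops (", x$n_dropped, " dropped), ",
      nrow(x$aggregate), "x", ncol(x$aggregate), " window, ", x$stat,
      " aggregate\n", sep = "")
  cat("  apa_score = ", format(apa_score(x)), ", meta_score = ",
      format(meta_score(x)), "\n", sep = "")
  invisible(x)
}

## 5x5 corner blocks of a (2f+1)-square window, by display position.
corner_block <- function(m, which = c("lower_right", "lower_left",
                                      "upper_right", "upper_left"),
                         size = 5) {
  which <- match.arg(which)
  w <- nrow(m)
  rows <- switch(which,
                 lower_right = , lower_left = (w - size + 1):w,
                 upper_right = , upper_left = 1:size)
  cols <- switch(which,
                 lower_right = , upper_right = (w - size + 1):w,
                 lower_left = , upper_left = 1:size)
  m[rows, cols, drop = FALSE]
}

#' APA score of an aggregate stack
#'
#' Center pixel divided by the mean of the 25 (5x5) pixels in the lower-right
#' section of the aggregate window. The alternative lower-left corner (the
#' Juicer convention) is available via `corner`.
#'
#' @param stack an `apa_stack` (or a bare aggregate matrix).
#' @param corner which 5x5 block to use as background.
#' @return the score; `NaN` (with a warning) when the corner mean is <= 0.
#' @export
apa_score <- function(stack, corner = c("lower_right", "lower_left")) {
  corner <- match.arg(corner)
  m <- if (inherits(stack, "apa_stack")) stack$aggregate else stack
  c0 <- (nrow(m) + 1) %/% 2
  bg <- mean(corner_block(m, corner))
  if (!is.finite(bg) || bg <= 0) {
    warning("APA corner mean <= 0; score undefined")
    return(NaN)
  }
  m[c0, c0] / bg
}

#' Meta score of an aggregate stack
#'
#' Center pixel divided by the median of the four pixels in the top-right
#' corner (2x2 block) of the window.
#'
#' @param stack an `apa_stack` (or a bare aggregate matrix).
#' @return the score; `NaN` (with a warning) when the corner median is 0.
#' @export
meta_score <- function(stack) {
  m <- if (inherits(stack, "apa_stack")) stack$aggregate else stack
  c0 <- (nrow(m) + 1) %/% 2
  w <- ncol(m)
  bg <- stats::median(m[1:2, (w - 1):w])
  if (!is.finite(bg) || bg == 0) {
    warning("meta-score corner median is 0; score undefined")
    return(NaN)
  }
  m[c0, c0] / bg
}

#' Corner-category differences between two aggregate stacks
#'
#' Difference (`b - a`) of average signal in three 5x5 corner regions of the
#' aggregate window: category 1 = top-left (inside-outside, left of loop),
#' category 2 = bottom-right (inside-outside, right of loop), category 3 =
#' top-right (crossing over the loop).
#'
#' @param stack_a,stack_b `apa_stack` objects (or aggregate matrices) with
#'   identical geometry.
#' @return named numeric vector `c(category1, category2, category3)`.
#' @export
corner_categories <- function(stack_a, stack_b) {
  a <- if (inherits(stack_a, "apa_stack")) stack_a$aggregate else stack_a
  b <- if (inherits(stack_b, "apa_stack")) stack_b$aggregate else stack_b
  if (!identical(dim(a), dim(b))) stop("window geometry mismatch")
  f <- function(m, corner) mean(corner_block(m, corner))
  c(category1 = f(b, "upper_left") - f(a, "upper_left"),
    category2 = f(b, "lower_right") - f(a, "lower_right"),
    category3 = f(b, "upper_right") - f(a, "upper_right"))
}

## Length-weighted rescaling weights: map L source bins onto n_scaled equal
## bins. Row k of the returned (n_scaled x L) matrix holds the fraction of
## scaled bin k covered by each source bin (rows sum to 1).
scale_weights <- function(L, n_scaled = 10) {
  W <- matrix(0, n_scaled, L)
  step <- L / n_scaled
  for (k in seq_len(n_scaled)) {
    lo <- (k - 1) * step
    hi <- k * step
    b0 <- floor(lo)
    b1 <- ceiling(hi) - 1
    for (b in b0:b1) {
      ov <- min(hi, b + 1) - max(lo, b)
      if (ov > 0) W[k, b + 1] <- ov / step
    }
  }
  W
}

#' Scaled multi-anchor metaplot comparing two matrices
#'
#' For each loop the inter-anchor span is rescaled to 10 equal bins (by
#' length-weighted pixel averaging on both matrix axes), flanked by a fixed
#' number of unscaled bins, so loops of any span map to one common grid. The
#' comparison (`subtract`: b - a; `log2fc`: log2(b/a) with non-positive
#' pixels floored at a small pseudocount) is computed per loop first and then
#' summarized by the per-pixel median across loops. Both matrices should be
#' depth-matched (subsampled) and VCsqrt-balanced beforehand. Loops whose
#' span covers fewer than 10 source bins are dropped and counted. For
#' multi-anchor (e.g. three-anchor) sets, pass `flip` so that the stable
#' anchors sit leftmost; flipped loops have both window axes reversed.
#'
#' @param cm_a,cm_b `contact_matrix` objects on the same layout (control,
#'   treatment).
#' @param loops a `loop_set`.
#' @param mode `"subtract"` or `"log2fc"`.
#' @param flank_bins fixed flank width in source bins.
#' @param n_scaled number of equal bins the span is scaled to.
#' @param flip optional logical per loop; `TRUE` reverses the loop's window.
#' @param pseudocount floor for non-positive pixels in `log2fc` mode.
#' @return an object of class `scaled_loop_matrix` with the `summary` grid,
#'   per-loop grids, and drop counts.
#' @export
scaled_multi_anchor_metaplot <- function(cm_a, cm_b, loops,
                                         mode = c("subtract", "log2fc"),
                                         flank_bins = 5, n_scaled = 10,
                                         flip = NULL, pseudocount = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm_a, "contact_matrix"), inherits(cm_b, "contact_matrix"),
            cm_a$n_bins == cm_b$n_bins, inherits(loops, "loop_set"))
  da <- cm_dense(cm_a); db <- cm_dense(cm_b)
  n <- cm_a$n_bins
  ab <- loop_anchor_bins(loops, cm_a$bin_size)
  if (is.null(flip)) flip <- rep(FALSE, nrow(loops))
  grids <- list()
  n_dropped <- 0
  for (k in seq_len(nrow(loops))) {
    i <- ab$bin1[k]; j <- ab$bin2[k]
    L <- j - i
    src0 <- i - flank_bins
    src1 <- j + flank_bins - 1
    if (L < n_scaled || src0 < 0 || src1 > n - 1) {
      n_dropped <- n_dropped + 1
      next
    }
    W <- scale_weights(L, n_scaled)
    nsrc <- src1 - src0 + 1
    B <- matrix(0, flank_bins * 2 + n_scaled, nsrc)
    B[seq_len(flank_bins), seq_len(flank_bins)] <- diag(flank_bins)
    B[flank_bins + seq_len(n_scaled), flank_bins + seq_len(L)] <- W
    B[flank_bins + n_scaled + seq_len(flank_bins),
      flank_bins + L + seq_len(flank_bins)] <- diag(flank_bins)
    src <- (src0:src1) + 1L
    Sa <- B %*% da[src, src] %*% t(B)
    Sb <- B %*% db[src, src] %*% t(B)
    g <- if (mode == "subtract") {
      Sb - Sa
    } else {
      log2(pmax(Sb, pseudocount) / pmax(Sa, pseudocount))
    }
    if (flip[k]) g <- g[rev(seq_len(nrow(g))), rev(seq_len(ncol(g)))]
    grids[[length(grids) + 1]] <- g
  }
  if (!length(grids)) stop("no loops retained for scaled metaplot")
  arr <- simplify2array(grids)
  structure(list(summary = apply(arr, c(1, 2), stats::median),
                 per_loop = arr, n_loops = length(grids),
                 n_dropped = n_dropped, flank_bins = flank_bins,
                 n_scaled = n_scaled, mode = mode),
            class = "scaled_loop_matrix")
}
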