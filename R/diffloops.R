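#' Merge per-stage loop calls into a union list
#'
#' Combines candidate loops from all stages, collapsing duplicates: loops
#' whose anchor-center bins (at `merge_resolution`) are within
#' `tolerance_bins` in both anchors form one cluster (transitively), kept as
#' the record from the earliest stage. Provenance records which stages called
#' each merged loop.
#'
#' @param per_stage_loops named list (stage -> `loop_set`), in stage order.
#' @param merge_resolution bin size (bp) at which anchors are compared.
#' @param tolerance_bins center distance (bins) treated as the same anchor.
#' @return a `loop_set` with columns `stages` (comma-separated provenance)
#'   and `n_stages`.
#' @export
merge_loop_calls <- function(per_stage_loops, merge_resolution,
                             tolerance_bins = 1) {
  stopifnot(is.list(per_stage_loops), length(per_stage_loops) >= 1)
  stages <- names(per_stage_loops)
  if (is.null(stages)) stages <- as.character(seq_along(per_stage_loops))
  all <- do.call(rbind, lapply(seq_along(per_stage_loops), function(s) {
    ls <- per_stage_loops[[s]]
    if (nrow(ls) == 0) return(NULL)
    data.frame(chrom = ls$chrom, start1 = ls$start1, end1 = ls$end1,
               start2 = ls$start2, end2 = ls$end2, stage = stages[s],
               stage_idx = s, stringsAsFactors = FALSE)
  }))
  if (is.null(all)) stop("no loops to merge")
  ab <- loop_anchor_bins(all, merge_resolution)
  comp <- cluster_loop_bins(all$chrom, ab$bin1, ab$bin2, tolerance_bins)
  reps <- vapply(split(seq_len(nrow(all)), comp), function(ix) {
    ix[which.min(all$stage_idx[ix])]
  }, 0L)
  prov <- vapply(split(all$stage, comp), function(s) {
    paste(stages[sort(unique(match(s, stages)))], collapse = ",")
  }, "")
  out <- all[reps, c("chrom", "start1", "end1", "start2", "end2")]
  out$stages <- prov
  out$n_stages <- lengths(strsplit(prov, ","))
  rownames(out) <- NULL
  class(out) <- c("loop_set", "data.frame")
  out
}

## Connected components of the "same loop" relation: same chromosome and
## both anchor-center bins within tol. Grid-bucketed union-find.
cluster_loop_bins <- function(chrom, bin1, bin2, tol) {
  n <- length(bin1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(chrom, bin1 %/% (tol + 1), bin2 %/% (tol + 1))
  buckets <- split(seq_len(n), key)
  bucket_of <- function(c, b1, b2) paste(c, b1, b2)
  for (i in seq_len(n)) {
    g1 <- bin1[i] %/% (tol + 1)
    g2 <- bin2[i] %/% (tol + 1)
    for (d1 in -1:1) for (d2 in -1:1) {
      cand <- buckets[[bucket_of(chrom[i], g1 + d1, g2 + d2)]]
      for (j in cand) {
        if (j >= i) next
        if (chrom[j] == chrom[i] && abs(bin1[j] - bin1[i]) <= tol &&
            abs(bin2[j] - bin2[i]) <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Quantify loops across stage/replicate matrices
#'
#' For every loop and every matrix, sums the raw (subsampled) counts over the
#' `(2*radius+1)` square pixel neighborhood around the loop pixel; the
#' default radius of 1 bin absorbs anchor-center jitter. When normalized
#' matrices are supplied the mean normalized value over the same neighborhood
#' is recorded for fold-change reporting and stage assignment.
#'
#' @param union a `loop_set` (the merged union).
#' @param matrices nested list: `matrices[[stage]][[replicate]]`, raw or
#'   subsampled `contact_matrix` objects.
#' @param norm_matrices optional same-shaped list of normalized (e.g.
#'   KR + distance-normalized) matrices.
#' @param radius neighborhood radius in bins (0 = single pixel).
#' @return an object of class `loop_counts`: arrays `counts` and `normalized`
#'   of dim loops x stages x replicates, the `loops`, stage names.
#' @export
quantify_loops <- function(union, matrices, norm_matrices = NULL, radius = 1) {
  stopifnot(inherits(union, "loop_set"))
  stages <- names(matrices)
  n_stage <- length(matrices)
  n_rep <- length(matrices[[1]])
  nL <- nrow(union)
  counts <- array(NA_real_, dim = c(nL, n_stage, n_rep),
                  dimnames = list(NULL, stages, NULL))
  normalized <- array(NA_real_, dim = dim(counts),
                      dimnames = dimnames(counts))
  bin_size <- matrices[[1]][[1]]$bin_size
  ab <- loop_anchor_bins(union, bin_size)
  for (s in seq_len(n_stage)) for (r in seq_len(n_rep)) {
    cm <- matrices[[s]][[r]]
    counts[, s, r] <- window_sums(cm, ab$bin1, ab$bin2, radius)
    if (!is.null(norm_matrices)) {
      normalized[, s, r] <- window_sums(norm_matrices[[s]][[r]],
                                        ab$bin1, ab$bin2, radius,
                                        stat = "mean")
    }
  }
  structure(list(counts = counts, normalized = normalized, loops = union,
                 stages = stages, radius = radius),
            class = "loop_counts")
}

## Neighborhood sums/means on the symmetric dense matrix; loops outside the
## matrix are flagged NA (missing).
window_sums <- function(cm, bin1, bin2, radius, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  dense <- cm_dense(cm)
  n <- cm$n_bins
  out <- numeric(length(bin1))
  inside <- bin1 - radius >= 0 & bin2 + radius <= n - 1 &
    bin1 + radius <= n - 1 & bin2 - radius >= 0
  out[!inside] <- NA_real_
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  acc <- matrix(0, sum(inside), nrow(offs))
  ii <- bin1[inside] + 1L
  jj <- bin2[inside] + 1L
  for (o in seq_len(nrow(offs))) {
    acc[, o] <- dense[cbind(ii + offs$di[o], jj + offs$dj[o])]
  }
  out[inside] <- if (stat == "sum") rowSums(acc) else rowMeans(acc)
  out
}

#' Exact negative-binomial test for two groups of counts at equal depth
#'
#' Two-sided exact test of equal means for replicate counts from two
#' conditions whose library sizes have been equalized by subsampling, under a
#' negative binomial with a common dispersion. Conditional on the grand
#' total, the group-A total follows a negative hypergeometric (beta-binomial)
#' law, reducing to the binomial when `dispersion = 0`; the p-value is the
#' doubled smaller tail, capped at 1.
#'
#' @param counts_a,counts_b integer replicate counts.
#' @param dispersion common NB dispersion (>= 0; 0 = Poisson/binomial exact).
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion = 0) {
  stopifnot(dispersion >= 0, all(counts_a >= 0), all(counts_b >= 0))
  nb_exact_test_sums(sum(counts_a), sum(counts_b),
                     length(counts_a), length(counts_b), dispersion)
}

## Internal: p-value from group sums and replicate numbers.
nb_exact_test_sums <- function(sa, sb, na, nb, dispersion) {
  t <- sa + sb
  if (t == 0) return(1)
  if (dispersion == 0) {
    pr <- na / (na + nb)
    pl <- stats::pbinom(sa, t, pr)
    pu <- 1 - stats::pbinom(sa - 1, t, pr)
    return(min(1, 2 * min(pl, pu)))
  }
  ra <- na / dispersion
  rb <- nb / dispersion
  x <- 0:t
  logw <- lgamma(x + ra) - lgamma(x + 1) - lgamma(ra) +
    lgamma(t - x + rb) - lgamma(t - x + 1) - lgamma(rb)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  pl <- sum(w[x <= sa])
  pu <- sum(w[x >= sa])
  min(1, 2 * min(pl, pu))
}

#' Method-of-moments common dispersion across loops
#'
#' Pools, over all loop x stage cells with at least two replicates, the
#' moment relation `var = mean + dispersion * mean^2` into a single
#' regression-through-origin estimate, floored at zero.
#'
#' @param counts loops x stages x replicates array of raw counts.
#' @return estimated common dispersion (scalar, >= 0).
#' @export
estimate_dispersion <- function(counts) {
  stopifnot(length(dim(counts)) == 3)
  if (dim(counts)[3] < 2)
    stop("dispersion cannot be estimated from a single replicate per stage; ",
         "supply it explicitly")
  num <- 0; den <- 0
  for (s in seq_len(dim(counts)[2])) {
    x <- counts[, s, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = dim(counts)[3])
    m <- rowMeans(x, na.rm = TRUE)
    v <- apply(x, 1, stats::var, na.rm = TRUE)
    ok <- is.finite(m) & is.finite(v) & m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  max(0, num / den)
}

#' Call differential vs common loops across all stage pairs
#'
#' For each unordered stage pair, each loop's replicate-summed counts are
#' compared with [nb_exact_test()]; Benjamini-Hochberg FDR is computed across
#' loops within each pair. A loop is differential when any stage pair passes
#' all three gates (p-value, FDR, fold change in either direction); all other
#' loops are common. Fold change is computed on group mean counts with a
#' pseudocount of 0.5 per group.
#'
#' @param lc a `loop_counts` object.
#' @param fdr,p_value,fold_change threshold gates (defaults 0.1, 0.05, 4).
#' @param dispersion common NB dispersion; estimated by [estimate_dispersion()]
#'   when `NULL`.
#' @return an object of class `loop_diff` with per-loop labels and per-pair
#'   statistics; see [assign_stage()] for gained/lost stage assignment.
#' @export
call_differential <- function(lc, fdr = 0.1, p_value = 0.05, fold_change = 4,
                              dispersion = NULL) {
  stopifnot(inherits(lc, "loop_counts"))
  counts <- lc$counts
  nL <- dim(counts)[1]; nS <- dim(counts)[2]; nR <- dim(counts)[3]
  if (nS < 2) stop("need at least two stages")
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts)
  pairs <- utils::combn(nS, 2)
  pmat <- fdrmat <- fcmat <- matrix(NA_real_, nL, ncol(pairs))
  pair_names <- apply(pairs, 2, function(x)
    paste(lc$stages[x[1]], lc$stages[x[2]], sep = "_vs_"))
  colnames(pmat) <- colnames(fdrmat) <- colnames(fcmat) <- pair_names
  for (k in seq_len(ncol(pairs))) {
    s1 <- pairs[1, k]; s2 <- pairs[2, k]
    a <- counts[, s1, , drop = FALSE]; dim(a) <- c(nL, nR)
    b <- counts[, s2, , drop = FALSE]; dim(b) <- c(nL, nR)
    sa <- rowSums(a); sb <- rowSums(b)
    ok <- is.finite(sa) & is.finite(sb)
    pv <- rep(NA_real_, nL)
    pv[ok] <- vapply(which(ok), function(i)
      nb_exact_test_sums(sa[i], sb[i], nR, nR, dispersion), 0)
    ma <- rowMeans(a) + 0.5
    mb <- rowMeans(b) + 0.5
    fc <- pmax(mb / ma, ma / mb)
    pmat[, k] <- pv
    fdrmat[, k] <- stats::p.adjust(pv, method = "BH")
    fcmat[, k] <- fc
  }
  hit <- pmat < p_value & fdrmat < fdr & fcmat >= fold_change
  differential <- rowSums(hit, na.rm = TRUE) > 0
  res <- data.frame(
    label = ifelse(differential, "differential", "common"),
    p_min = apply(pmat, 1, min, na.rm = TRUE),
    fdr_min = apply(fdrmat, 1, min, na.rm = TRUE),
    fc_max = apply(fcmat, 1, max, na.rm = TRUE)
  )
  structure(list(loops = lc$loops, result = res, p = pmat, fdr = fdrmat,
                 fc = fcmat, stages = lc$stages, dispersion = dispersion,
                 thresholds = c(fdr = fdr, p_value = p_value,
                                fold_change = fold_change),
                 counts = lc$counts, normalized = lc$normalized),
            class = "loop_diff")
}

#' Assign differential loops to a stage and a direction
#'
#' Gained vs lost is decided by the sign of the largest-magnitude
#' consecutive-stage change in the loop's mean normalized contact frequency
#' profile; a gained loop is then assigned to the stage where the profile
#' peaks and a lost loop to the stage where it bottoms. Exact ties go to the
#' earliest stage in developmental order and are flagged.
#'
#' @param ld a `loop_diff` object.
#' @param norm_freq optional loops x stages matrix of per-stage mean
#'   normalized frequencies; defaults to the stage means of the normalized
#'   values carried by the object (falling back to raw count means).
#' @return `ld` with columns `direction`, `assigned_stage`, `tie` added to
#'   `$result`.
#' @export
assign_stage <- function(ld, norm_freq = NULL) {
  stopifnot(inherits(ld, "loop_diff"))
  if (is.null(norm_freq)) {
    src <- if (!all(is.na(ld$normalized))) ld$normalized else ld$counts
    norm_freq <- apply(src, c(1, 2), mean)
  }
  nL <- nrow(norm_freq)
  res <- ld$result
  res$direction <- NA_character_
  res$assigned_stage <- NA_character_
  res$tie <- FALSE
  diffidx <- which(res$label == "differential")
  for (i in diffidx) {
    prof <- norm_freq[i, ]
    if (all(!is.finite(prof))) next
    deltas <- diff(prof)
    big <- which.max(abs(deltas))  # earliest wins on exact tie
    gained <- deltas[big] > 0
    res$direction[i] <- if (gained) "gained" else "lost"
    target <- if (gained) max(prof) else min(prof)
    hits <- which(prof == target)
    res$assigned_stage[i] <- ld$stages[hits[1]]
    res$tie[i] <- length(hits) > 1 ||
      sum(abs(deltas) == abs(deltas[big])) > 1
  }
  ld$result <- res
  ld
}

#' @export
print.loop_diff <- function(x, ...) {
  n <- nrow(x$result)
  nd <- sum(x$result$label == "differential")
  cat("loop_diff: ", n, " loops over ", length(x$stages), " stages (",
      paste(x$stages, collapse = " -> "), ")\n", sep = "")
  cat("  differential: ", nd, ", common: ", n - nd,
      " (FDR < ", x$thresholds["fdr"], ", p < ", x$thresholds["p_value"],
      ", FC >= ", x$thresholds["fold_change"], ")\n", sep = "")
  cat("  common NB dispersion: ", format(x$dispersion, digits = 4), "\n",
      sep = "")
  if ("direction" %in% names(x$result)) {
    tab <- table(x$result$direction, x$result$assigned_stage)
    if (length(tab)) print(tab)
  }
  invisible(x)
}

#' @export
summary.loop_diff <- function(object, ...) {
  res <- object$result
  out <- list(
    n_loops = nrow(res),
    n_differential = sum(res$label == "differential"),
    n_common = sum(res$label == "common"),
    dispersion = object$dispersion,
    thresholds = object$thresholds,
    by_stage = if ("assigned_stage" %in% names(res))
      table(direction = res$direction, stage = res$assigned_stage)
  )
  class(out) <- "summary.loop_diff"
  out
}

#' @export
print.summary.loop_diff <- function(x, ...) {
  cat("Differential loop summary\n")
  cat("  loops:", x$n_loops, "| differential:", x$n_differential,
      "| common:", x$n_common, "\n")
  cat("  dispersion:", format(x$dispersion, digits = 4), "\n")
  if (!is.null(x$by_stage)) print(x$by_stage)
  invisible(x)
}
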