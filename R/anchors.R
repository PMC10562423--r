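## Anchors of a loop_set as a GRanges (both ends), optionally padded.
anchors_granges <- function(loops, pad = 0) {
  GenomicRanges::GRanges(
    seqnames = rep(loops$chrom, 2),
    ranges = IRanges::IRanges(
      start = c(loops$start1, loops$start2) + 1L - pad,
      end = c(loops$end1, loops$end2) + pad),
    loop = rep(seq_len(nrow(loops)), 2),
    side = rep(1:2, each = nrow(loops)))
}

#' Annotate loops with anchor peak occupancy
#'
#' An anchor is occupied when the anchor interval padded by `anchor_pad`
#' (default +/- 5 kb) intersects at least one peak; loops are classed as
#' having the factor at `both`, `one` or `none` of their anchors.
#'
#' @param loops a `loop_set`.
#' @param peaks a `GRanges` peak set.
#' @param anchor_pad padding in bp added to each side of each anchor.
#' @return list with `per_loop` (data.frame: `hit1`, `hit2`, `class`) and
#'   `fractions` (named fractions of loops in each class).
#' @export
annotate_occupancy <- function(loops, peaks, anchor_pad = 5000) {
  stopifnot(inherits(loops, "loop_set"))
  anc <- anchors_granges(loops, pad = anchor_pad)
  hit <- IRanges::overlapsAny(anc, peaks)
  n <- nrow(loops)
  hit1 <- hit[seq_len(n)]
  hit2 <- hit[n + seq_len(n)]
  cls <- ifelse(hit1 & hit2, "both", ifelse(hit1 | hit2, "one", "none"))
  frac <- c(both = mean(cls == "both"), one = mean(cls == "one"),
            none = mean(cls == "none"))
  list(per_loop = data.frame(hit1 = hit1, hit2 = hit2, class = cls),
       fractions = frac)
}

#' Permutation test of anchor/peak overlap
#'
#' Observed statistic: fraction of anchors overlapping at least one peak.
#' Peaks are shuffled uniformly within their own chromosome (lengths
#' preserved, overlaps between shuffled peaks allowed) and the statistic
#' recomputed. Two p-values are reported: `p_literal`, the number of shuffles
#' in which the observed ratio falls below the shuffled ratio divided by the
#' number of shuffles (a depletion-style rule without the +1 correction),
#' and `p_enrichment = (1 + #\{shuffled >= observed\}) / (n + 1)`, the
#' standard add-one permutation p-value for enrichment.
#'
#' @param anchors a `GRanges` of (already padded) anchor intervals.
#' @param peaks a `GRanges` peak set.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed optional integer seed.
#' @return list: `observed`, `expected` (mean shuffled ratio), `p_literal`,
#'   `p_enrichment`, `shuffled` (the per-shuffle ratios).
#' @export
shuffle_overlap_test <- function(anchors, peaks, chrom_lengths,
                                 n_shuffles = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  wid <- GenomicRanges::width(peaks)
  lens <- chrom_lengths[chr]
  if (any(is.na(lens))) stop("peak on chromosome absent from chrom_lengths")
  if (any(wid > lens))
    stop("chromosome shorter than a peak; cannot shuffle")
  observed <- mean(IRanges::overlapsAny(anchors, peaks))
  ## all shuffles in one overlap query: peaks relocated uniformly within
  ## their own chromosome, then hits restricted to the matching shuffle
  nP <- length(peaks)
  nA <- length(anchors)
  st <- floor(stats::runif(nP * n_shuffles,
                           min = 0, max = rep(lens - wid + 1, n_shuffles)))
  allperm <- GenomicRanges::GRanges(
    seqnames = rep(chr, n_shuffles),
    ranges = IRanges::IRanges(start = st + 1, width = rep(wid, n_shuffles)))
  shuffle_id <- rep(seq_len(n_shuffles), each = nP)
  fo <- GenomicRanges::findOverlaps(anchors, allperm)
  key <- unique((shuffle_id[S4Vectors::subjectHits(fo)] - 1) * nA +
                  S4Vectors::queryHits(fo))
  shuffled <- tabulate((key - 1) %/% nA + 1, nbins = n_shuffles) / nA
  list(observed = observed,
       expected = mean(shuffled),
       p_literal = sum(observed < shuffled) / n_shuffles,
       p_enrichment = (1 + sum(shuffled >= observed)) / (n_shuffles + 1),
       shuffled = shuffled)
}

#' Classify how a new loop relates to the previous stage's anchors
#'
#' Each loop newly present at stage *t* is compared against the loops of
#' stage *t-1*. Anchor identity is matched on anchor-center bins within
#' `tolerance_bins` at `bin_size` resolution. Categories (mutually exclusive,
#' exhaustive):
#' \describe{
#'   \item{both_anchors_new}{neither anchor matches any prior loop anchor.}
#'   \item{extension_one_anchor}{exactly one anchor matches a prior loop
#'     anchor and the new partner lies strictly outside that prior loop's
#'     span on the far side of the shared anchor (the loop grew).}
#'   \item{paired_new_anchor_split}{exactly one anchor matches a prior loop
#'     anchor and the new partner lies strictly inside the prior span
#'     (the prior loop was split at a new internal anchor).}
#'   \item{other}{anything else (e.g. both anchors reused in a new pairing).}
#' }
#'
#' @param new_loops,prior_loops `loop_set` objects.
#' @param bin_size resolution (bp) for anchor matching.
#' @param tolerance_bins anchor-center distance (bins) counted as a match.
#' @return data.frame with `category` and the matched prior-loop index used
#'   as evidence (`NA` when none).
#' @export
classify_anchor_change <- function(new_loops, prior_loops, bin_size,
                                   tolerance_bins = 1) {
  stopifnot(inherits(new_loops, "loop_set"), inherits(prior_loops, "loop_set"))
  pb <- loop_anchor_bins(prior_loops, bin_size)
  nb <- loop_anchor_bins(new_loops, bin_size)
  n <- nrow(new_loops)
  category <- character(n)
  evidence <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    same_chr <- prior_loops$chrom == new_loops$chrom[i]
    m1 <- same_chr & (abs(pb$bin1 - nb$bin1[i]) <= tolerance_bins |
                      abs(pb$bin2 - nb$bin1[i]) <= tolerance_bins)
    m2 <- same_chr & (abs(pb$bin1 - nb$bin2[i]) <= tolerance_bins |
                      abs(pb$bin2 - nb$bin2[i]) <= tolerance_bins)
    a1_matched <- any(m1)
    a2_matched <- any(m2)
    if (!a1_matched && !a2_matched) {
      category[i] <- "both_anchors_new"
      next
    }
    if (a1_matched && a2_matched) {
      category[i] <- "other"
      next
    }
    ## exactly one anchor shared with a prior loop
    shared_bin <- if (a1_matched) nb$bin1[i] else nb$bin2[i]
    partner_bin <- if (a1_matched) nb$bin2[i] else nb$bin1[i]
    cands <- which(if (a1_matched) m1 else m2)
    cat_i <- "other"
    for (j in cands) {
      shared_left <- abs(pb$bin1[j] - shared_bin) <= tolerance_bins
      old_partner <- if (shared_left) pb$bin2[j] else pb$bin1[j]
      inside <- partner_bin > min(pb$bin1[j], pb$bin2[j]) &&
        partner_bin < max(pb$bin1[j], pb$bin2[j])
      beyond <- if (shared_left) partner_bin > old_partner
                else partner_bin < old_partner
      if (beyond) {
        cat_i <- "extension_one_anchor"
        evidence[i] <- j
        break
      }
      if (inside && cat_i == "other") {
        cat_i <- "paired_new_anchor_split"
        evidence[i] <- j
      }
    }
    category[i] <- cat_i
  }
  data.frame(category = category, matched_prior = evidence)
}

#' Rank loops by the position of an internal co-occupied site
#'
#' The co-occupied sites are the intersections of two peak sets (e.g.
#' NIPBL and RAD21). For each loop, sites strictly inside the span (between
#' anchor1 end and anchor2 start) are found; when several exist the one
#' nearest the left anchor is used and the multiplicity reported. The site is
#' mapped to a scaled coordinate in `[0, 1]` between the two anchor
#' midpoints, and loops are ordered by their left-anchor-to-site distance;
#' loops without an internal site are grouped last.
#'
#' @param loops a `loop_set`.
#' @param peaks_a,peaks_b `GRanges` peak sets whose intersection defines
#'   co-occupied sites.
#' @return data.frame (one row per loop, ordered) with `loop`, `has_site`,
#'   `site_mid`, `scaled_pos`, `dist_left`, `n_internal_sites`.
#' @export
rank_by_internal_site <- function(loops, peaks_a, peaks_b) {
  stopifnot(inherits(loops, "loop_set"))
  sites <- GenomicRanges::intersect(peaks_a, peaks_b)
  n <- nrow(loops)
  mids <- loop_anchor_mids(loops)
  out <- data.frame(loop = seq_len(n), has_site = FALSE,
                    site_mid = NA_real_, scaled_pos = NA_real_,
                    dist_left = NA_real_, n_internal_sites = 0L)
  if (length(sites)) {
    schr <- as.character(GenomicRanges::seqnames(sites))
    s0 <- GenomicRanges::start(sites) - 1L
    s1 <- GenomicRanges::end(sites)
    smid <- (s0 + s1) / 2
    for (i in seq_len(n)) {
      inside <- schr == loops$chrom[i] & s0 >= loops$end1[i] &
        s1 <= loops$start2[i]
      k <- sum(inside)
      out$n_internal_sites[i] <- k
      if (k == 0) next
      d <- smid[inside] - mids$mid1[i]
      best <- which.min(d)
      out$has_site[i] <- TRUE
      out$site_mid[i] <- smid[inside][best]
      out$dist_left[i] <- d[best]
      out$scaled_pos[i] <- d[best] / (mids$mid2[i] - mids$mid1[i])
    }
  }
  ord <- order(!out$has_site, out$dist_left)
  out[ord, ]
}
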