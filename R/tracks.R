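#' Tn5-shift ATAC fragments and partition by insert size
#'
#' Fragment 5' ends on the + strand are shifted +4 bp and on the - strand
#' -5 bp (each fragment's start is moved +4 and its end -5, since the - read's
#' 5' end is the fragment end), correcting for the 9-bp Tn5 duplication.
#' Shifted inserts of 50-115 bp (inclusive) are sub-nucleosomal
#' ("ATAC-TF"), 180-247 bp are mono-nucleosomal ("ATAC-Nuc"); everything
#' else is discarded with a count.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param tf_range,nuc_range inclusive insert-size gates in bp.
#' @return list: `tf` and `nuc` (shifted fragment data.frames with `length`),
#'   `n_discarded`, `n_total`.
#' @export
shift_and_partition_atac <- function(fragments,
                                     tf_range = c(50, 115),
                                     nuc_range = c(180, 247)) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(fragments)))
  if (any(fragments$start >= fragments$end))
    stop("fragment with start >= end")
  st <- fragments$start + 4L
  en <- fragments$end - 5L
  if (any(st < 0)) {
    warning(sum(st < 0), " fragment start(s) clipped at 0 after shift")
    st <- pmax(st, 0L)
  }
  len <- en - st
  df <- data.frame(chrom = fragments$chrom, start = st, end = en,
                   strand = fragments$strand, length = len,
                   stringsAsFactors = FALSE)
  ok <- len > 0
  tf <- ok & len >= tf_range[1] & len <= tf_range[2]
  nuc <- ok & len >= nuc_range[1] & len <= nuc_range[2]
  list(tf = df[tf, , drop = FALSE],
       nuc = df[nuc, , drop = FALSE],
       n_discarded = sum(!(tf | nuc)),
       n_total = nrow(df))
}

#' Reads-per-million bin matrix around anchors
#'
#' Builds the anchors x bins matrix of read counts in equal-width bins
#' spanning `center - flank` to `center + flank` around each anchor center,
#' divided by the library size in millions (RPM per bin). Reads are counted
#' in every bin they overlap. Anchors whose window leaves the chromosome are
#' masked (`NA` rows). Anchors on the minus strand have their rows reversed
#' when `strand_aware` is set.
#'
#' @param reads `GRanges` of reads/fragments.
#' @param anchors `GRanges` of anchor intervals (centers used).
#' @param flank half window width in bp.
#' @param bin_width bin width in bp (must divide `2*flank`).
#' @param library_size mapped reads backing the track; defaults to
#'   `length(reads)`.
#' @param chrom_lengths named chromosome lengths for edge masking (optional).
#' @param strand_aware reverse rows of minus-strand anchors.
#' @return object of class `bin_matrix`: `matrix` (RPM), `profile` (column
#'   means over unmasked rows), geometry fields.
#' @export
rpm_bin_matrix <- function(reads, anchors, flank, bin_width,
                           library_size = NULL, chrom_lengths = NULL,
                           strand_aware = FALSE) {
  if ((2 * flank) %% bin_width != 0)
    stop("bin_width must divide the window size 2*flank")
  if (is.null(library_size)) library_size <- length(reads)
  nb <- as.integer(2 * flank / bin_width)
  centers <- floor((GenomicRanges::start(anchors) - 1 +
                    GenomicRanges::end(anchors)) / 2)
  nA <- length(anchors)
  mat <- matrix(0, nA, nb)
  win_start <- centers - flank
  masked <- win_start < 0
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[as.character(GenomicRanges::seqnames(anchors))]
    masked <- masked | (centers + flank > lens)
  }
  for (b in seq_len(nb)) {
    bin_gr <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(anchors),
      ranges = IRanges::IRanges(start = win_start + (b - 1) * bin_width + 1,
                                width = bin_width))
    mat[, b] <- GenomicRanges::countOverlaps(bin_gr, reads)
  }
  mat <- mat / (library_size / 1e6)
  if (strand_aware) {
    neg <- as.character(GenomicRanges::strand(anchors)) == "-"
    mat[neg, ] <- mat[neg, rev(seq_len(nb)), drop = FALSE]
  }
  mat[masked, ] <- NA_real_
  structure(list(matrix = mat,
                 profile = colMeans(mat, na.rm = TRUE),
                 flank = flank, bin_width = bin_width,
                 library_size = library_size,
                 n_masked = sum(masked)),
            class = "bin_matrix")
}

#' Classify enhancers from histone-mark and accessibility peaks
#'
#' An enhancer is an H3K4me1 peak with no H3K4me3 overlap, overlapping at
#' least one ATAC-TF peak, and not overlapping any TSS padded by `tss_pad`
#' on each side. Enhancers overlapping an H3K27ac peak are additionally
#' active. The default pad of 1000 bp implements the usual promoter
#' exclusion; set `tss_pad = 1` for a literal single-bp exclusion zone.
#'
#' @param h3k4me1,h3k4me3,atac_tf,h3k27ac `GRanges` peak sets.
#' @param tss `GRanges` of TSS positions.
#' @param tss_pad promoter exclusion half-width in bp.
#' @return data.frame (one row per H3K4me1 peak): `enhancer`,
#'   `active_enhancer` logicals; attribute `"calls"` holds the enhancer
#'   `GRanges` with a `class` column.
#' @export
classify_enhancers <- function(h3k4me1, h3k4me3, atac_tf, h3k27ac, tss,
                               tss_pad = 1000) {
  tss_pad <- as.integer(tss_pad)
  tss_zone <- GenomicRanges::resize(tss,
                                    width = GenomicRanges::width(tss) +
                                      2L * tss_pad,
                                    fix = "center")
  enh <- !IRanges::overlapsAny(h3k4me1, h3k4me3) &
    IRanges::overlapsAny(h3k4me1, atac_tf) &
    !IRanges::overlapsAny(h3k4me1, tss_zone)
  act <- enh & IRanges::overlapsAny(h3k4me1, h3k27ac)
  out <- data.frame(enhancer = enh, active_enhancer = act)
  calls <- h3k4me1[enh]
  calls$class <- ifelse(act[enh], "active_enhancer", "enhancer")
  attr(out, "calls") <- calls
  out
}

#' Differential enhancers from H3K27ac counts
#'
#' Exact NB test (see [nb_exact_test()]) on per-enhancer replicate counts for
#' two conditions at matched depth; differential when `p < p_value` and the
#' fold change (pseudocount 0.5 per group mean) exceeds `fold_change` in
#' either direction.
#'
#' @param counts_a,counts_b matrices (enhancers x replicates) of counts.
#' @param dispersion common NB dispersion; method-of-moments estimate from
#'   the two groups when `NULL`.
#' @param p_value,fold_change gates (defaults 0.05 and 3).
#' @return data.frame: `p`, `fc`, `differential`.
#' @export
differential_enhancers <- function(counts_a, counts_b, dispersion = NULL,
                                   p_value = 0.05, fold_change = 3) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  stopifnot(nrow(counts_a) == nrow(counts_b))
  if (is.null(dispersion)) {
    arr <- array(NA_real_, dim = c(nrow(counts_a), 2,
                                   max(ncol(counts_a), ncol(counts_b))))
    arr[, 1, seq_len(ncol(counts_a))] <- counts_a
    arr[, 2, seq_len(ncol(counts_b))] <- counts_b
    dispersion <- estimate_dispersion(arr)
  }
  p <- vapply(seq_len(nrow(counts_a)), function(i)
    nb_exact_test(counts_a[i, ], counts_b[i, ], dispersion), 0)
  ma <- rowMeans(counts_a) + 0.5
  mb <- rowMeans(counts_b) + 0.5
  fc <- pmax(mb / ma, ma / mb)
  data.frame(p = p, fc = fc,
             differential = p < p_value & fc > fold_change)
}

#' H3K9me3-positive 25-kb bins from IP and input tracks
#'
#' Calls a bin positive when IP/input >= `ratio` (boundary inclusive). The
#' input is floored at one read per bin so empty input bins cannot divide by
#' zero. Both tracks must already be depth-normalized to equal library
#' sizes; the function does not rescale them.
#'
#' @param ip,input `signal_track` objects on the same bins.
#' @param ratio positivity threshold (default 4).
#' @return list: `positive` logical per bin, `ratio` numeric per bin.
#' @export
h3k9me3_positive_bins <- function(ip, input, ratio = 4) {
  stopifnot(inherits(ip, "signal_track"), inherits(input, "signal_track"),
            ip$n_bins == input$n_bins)
  r <- ip$values / pmax(input$values, 1)
  list(positive = r >= ratio, ratio = r)
}

#' Differential H3K9me3 bins between two stages
#'
#' A bin is differential when its IP/input ratio changes at least
#' `fold_change`-fold between the stages, in either direction; `gained`
#' means higher in stage B.
#'
#' @param ip_a,input_a,ip_b,input_b `signal_track` objects.
#' @param fold_change ratio-change threshold (default 4, inclusive).
#' @return list: `gained`, `lost` logical per bin, plus both per-stage
#'   ratios.
#' @export
h3k9me3_differential_bins <- function(ip_a, input_a, ip_b, input_b,
                                      fold_change = 4) {
  ra <- h3k9me3_positive_bins(ip_a, input_a)$ratio
  rb <- h3k9me3_positive_bins(ip_b, input_b)$ratio
  eps <- .Machine$double.eps
  gained <- rb >= fold_change * pmax(ra, eps) & rb > 0
  lost <- ra >= fold_change * pmax(rb, eps) & ra > 0
  list(gained = gained, lost = lost, ratio_a = ra, ratio_b = rb)
}

#' Expression change of genes inside loop sets
#'
#' A gene belongs to a loop when its body midpoint lies inside the loop span
#' (anchor1 start to anchor2 end). For each loop set the per-gene
#' `log2((TPM_stage + 1) / (TPM_prev + 1))` values of contained genes are
#' collected; loops containing no gene are excluded and counted.
#'
#' @param loops a `loop_set`.
#' @param genes `GRanges` with a `gene_id` column.
#' @param tpm data.frame with `gene_id` and one column per stage.
#' @param stage,prev_stage column names of the stage and its predecessor.
#' @return list: `log2fc` (per contained gene), `gene_loop` assignment
#'   data.frame, `quartiles`, `n_loops_without_genes`.
#' @export
expression_in_loops <- function(loops, genes, tpm, stage, prev_stage) {
  stopifnot(inherits(loops, "loop_set"),
            all(c(stage, prev_stage, "gene_id") %in%
                  c(names(tpm), "gene_id")))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gmid <- (GenomicRanges::start(genes) - 1 + GenomicRanges::end(genes)) / 2
  rows <- list()
  n_empty <- 0
  for (i in seq_len(nrow(loops))) {
    inside <- gchr == loops$chrom[i] & gmid >= loops$start1[i] &
      gmid < loops$end2[i]
    if (!any(inside)) {
      n_empty <- n_empty + 1
      next
    }
    rows[[length(rows) + 1]] <- data.frame(loop = i,
                                           gene_id = genes$gene_id[inside])
  }
  gene_loop <- if (length(rows)) do.call(rbind, rows) else
    data.frame(loop = integer(0), gene_id = character(0))
  idx <- match(gene_loop$gene_id, tpm$gene_id)
  lfc <- log2((tpm[[stage]][idx] + 1) / (tpm[[prev_stage]][idx] + 1))
  list(log2fc = lfc, gene_loop = gene_loop,
       quartiles = stats::quantile(lfc, c(0.25, 0.5, 0.75), na.rm = TRUE),
       n_loops_without_genes = n_empty)
}
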