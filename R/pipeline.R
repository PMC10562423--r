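#' Run the full loop-dynamics pipeline on synthetic data
#'
#' Orchestrates simulate -> subsample -> balance -> distance-normalize ->
#' merge/quantify/test/assign -> anchor annotation -> taxonomy -> APA ->
#' track analyses, writing every artifact (triplet matrices, BEDPE, TSV,
#' bedGraph) plus a checksummed manifest into `out_dir`. The run is a pure
#' function of `(config, thresholds)`; the seed inside `config` drives all
#' randomness.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [sim_config()]; its `seed` also seeds the shuffle test.
#' @param fdr,p_value,fold_change differential-loop gates (paper defaults
#'   0.1, 0.05, 4).
#' @param anchor_pad occupancy padding in bp (default 5000).
#' @param flank APA window half-width in bins (default 10).
#' @param n_shuffles permutation count for the anchor overlap test.
#' @param radius loop quantification neighborhood radius in bins.
#' @return invisibly, a list with the fitted `loop_diff` object, recovery
#'   statistics against the planted truth, APA scores, the occupancy and
#'   shuffle results, and the manifest data.frame.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         fdr = 0.1, p_value = 0.05, fold_change = 4,
                         anchor_pad = 5000, flank = 10, n_shuffles = 1000,
                         radius = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  S <- length(stages)

  ## 1. simulate
  sim <- simulate_stage_hic(config)
  truth <- sim$truth
  utils::write.table(truth, file.path(out_dir, "truth_loops.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## 2. depth-match all libraries, then balance + distance-normalize
  flat <- unlist(sim$matrices, recursive = FALSE)
  sub <- subsample_contacts(flat, seed = config$seed + 2L)
  norm <- lapply(sub, function(m) {
    kr <- balance(m, "KR")
    distance_normalize(kr, expected_by_distance(kr))
  })
  reshape <- function(x) {
    out <- list()
    k <- 0
    for (s in seq_len(S)) {
      out[[stages[s]]] <- lapply(seq_len(config$replicates), function(r) {
        x[[k + r]]
      })
      k <- k + config$replicates
    }
    out
  }
  sub_m <- reshape(sub)
  norm_m <- reshape(norm)
  for (s in stages) for (r in seq_len(config$replicates)) {
    write_contacts(sub_m[[s]][[r]],
                   file.path(out_dir, sprintf("contacts_%s_rep%d.txt", s, r)))
  }

  ## 3. union of per-stage candidate calls (planted truth stands in for the
  ##    loop caller), then the four-step differential pipeline
  bs <- config$bin_size
  mult_cols <- paste0("mult_", stages)
  per_stage <- stats::setNames(lapply(seq_len(S), function(s) {
    act <- truth[[mult_cols[s]]] > 1 | truth$label == "null"
    loop_set(chrom = rep(config$chrom, sum(act)),
             start1 = truth$bin1[act] * bs, end1 = (truth$bin1[act] + 1) * bs,
             start2 = truth$bin2[act] * bs, end2 = (truth$bin2[act] + 1) * bs)
  }), stages)
  union <- merge_loop_calls(per_stage, merge_resolution = bs)
  lc <- quantify_loops(union, sub_m, norm_m, radius = radius)
  ld <- call_differential(lc, fdr = fdr, p_value = p_value,
                          fold_change = fold_change)
  ld <- assign_stage(ld)
  out_loops <- cbind(union, ld$result)
  write_bedpe(out_loops, file.path(out_dir, "loops_labeled.bedpe"))
  utils::write.table(cbind(ld$result, ld$p, ld$fdr, ld$fc),
                     file.path(out_dir, "loop_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## 4. recovery against planted truth (union rows map 1:1 onto truth rows
  ##    by pixel since the planted pixels are unique)
  key_u <- paste(loop_anchor_bins(union, bs)$bin1,
                 loop_anchor_bins(union, bs)$bin2)
  key_t <- paste(truth$bin1, truth$bin2)
  tmap <- match(key_u, key_t)
  truth_lab <- truth$label[tmap]
  truth_stage <- truth$stage[tmap]
  called_diff <- ld$result$label == "differential"
  is_planted_diff <- truth_lab %in% c("gained", "lost")
  sensitivity <- mean(called_diff[is_planted_diff])
  precision <- if (any(called_diff)) mean(is_planted_diff[called_diff]) else NA
  hit <- called_diff & is_planted_diff
  stage_accuracy <- mean(ld$result$assigned_stage[hit] == truth_stage[hit])
  direction_accuracy <- mean(ld$result$direction[hit] == truth_lab[hit])
  recovery <- data.frame(sensitivity = sensitivity, precision = precision,
                         stage_accuracy = stage_accuracy,
                         direction_accuracy = direction_accuracy)
  utils::write.table(recovery, file.path(out_dir, "recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## 5. APA on the final-stage VCsqrt O/E map, planted vs null loops
  apa_loops <- function(rows) {
    loop_set(chrom = rep(config$chrom, sum(rows)),
             start1 = truth$bin1[rows] * bs, end1 = (truth$bin1[rows] + 1) * bs,
             start2 = truth$bin2[rows] * bs, end2 = (truth$bin2[rows] + 1) * bs)
  }
  vc <- balance(pool_replicates(sub_m[[S]]), "VCsqrt")
  nm1 <- distance_normalize(vc, method = "ratio")
  apa_common <- build_apa_stack(nm1, apa_loops(truth$label == "common"),
                                flank = flank)
  apa_null <- build_apa_stack(nm1, apa_loops(truth$label == "null"),
                              flank = flank)
  apa <- data.frame(set = c("common", "null"),
                    apa_score = c(apa_score(apa_common), apa_score(apa_null)),
                    meta_score = c(meta_score(apa_common),
                                   meta_score(apa_null)),
                    n_loops = c(apa_common$n_loops, apa_null$n_loops))
  utils::write.table(apa, file.path(out_dir, "apa_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## 6. anchor annotation on the last stage's active loops
  pk <- simulate_peaks_and_tracks(sim)
  act_last <- truth[[mult_cols[S]]] > 1
  loops_last <- apa_loops(act_last)
  occ <- annotate_occupancy(loops_last, pk$peaks[[S]]$CTCF,
                            anchor_pad = anchor_pad)
  chrom_lengths <- stats::setNames(config$n_bins * bs, config$chrom)
  shuf <- shuffle_overlap_test(anchors_granges(loops_last, pad = anchor_pad),
                               pk$peaks[[S]]$CTCF, chrom_lengths,
                               n_shuffles = n_shuffles,
                               seed = config$seed + 3L)
  ## 7. taxonomy of loops new at each stage vs the previous stage
  taxonomy <- list()
  for (s in 2:S) {
    new_rows <- truth[[mult_cols[s]]] > 1 & truth[[mult_cols[s - 1]]] <= 1
    prior_rows <- truth[[mult_cols[s - 1]]] > 1
    if (!any(new_rows) || !any(prior_rows)) next
    taxonomy[[stages[s]]] <- classify_anchor_change(
      apa_loops(new_rows), apa_loops(prior_rows), bin_size = bs)
  }

  ## 8. tracks: ATAC partition and enhancer classification on planted truth
  atac <- simulate_atac_fragments(2000, 1000, seed = config$seed + 4L)
  part <- shift_and_partition_atac(atac$fragments)
  enh <- classify_enhancers(pk$enhancers$H3K4me1, pk$enhancers$H3K4me3,
                            pk$enhancers$ATAC_TF, pk$enhancers$H3K27ac,
                            pk$enhancers$TSS)
  enh_calls <- attr(enh, "calls")
  if (length(enh_calls))
    write_bed(enh_calls, file.path(out_dir, "enhancers.bed"))

  ## manifest with checksums
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(diff = ld, recovery = recovery, apa = apa,
                 occupancy = occ, shuffle = shuf, taxonomy = taxonomy,
                 atac = part, enhancers = enh, truth = truth,
                 manifest = manifest))
}
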