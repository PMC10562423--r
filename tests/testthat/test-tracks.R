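test_that("ATAC shift-and-partition gates shifted insert sizes inclusively", {
  ## raw length = shifted length + 9
  mk <- function(lens) data.frame(chrom = "chrT", start = 1000L,
                                  end = 1000L + lens + 9L,
                                  strand = rep(c("+", "-"),
                                               length.out = length(lens)))
  part <- shift_and_partition_atac(mk(c(100, 200, 150, 50, 115, 49, 116,
                                        180, 247, 179, 248)))
  expect_equal(part$tf$length, c(100, 50, 115))
  expect_equal(part$nuc$length, c(200, 180, 247))
  expect_equal(part$n_discarded, 5)
  expect_equal(part$n_total, 11)
  ## shift arithmetic: start +4, end -5
  expect_equal(part$tf$start[1], 1004)
  expect_equal(part$tf$end[1], 1104)
})

test_that("ATAC partition is complete and matches a brute-force gate", {
  set.seed(61)
  lens <- sample(20:300, 500, replace = TRUE)
  frags <- data.frame(chrom = "chrT", start = sample(1e3:1e5, 500),
                      strand = sample(c("+", "-"), 500, replace = TRUE))
  frags$end <- frags$start + lens
  part <- shift_and_partition_atac(frags)
  shifted <- lens - 9
  expect_equal(nrow(part$tf), sum(shifted >= 50 & shifted <= 115))
  expect_equal(nrow(part$nuc), sum(shifted >= 180 & shifted <= 247))
  expect_equal(nrow(part$tf) + nrow(part$nuc) + part$n_discarded,
               part$n_total)
})

test_that("negative coordinates after shifting are clipped with a warning", {
  frags <- data.frame(chrom = "chrT", start = -10L, end = 200L, strand = "+")
  expect_warning(part <- shift_and_partition_atac(frags), "clipped")
  expect_gte(part$nuc$start[1], 0)
})

test_that("RPM matrices count reads per bin and scale with library size", {
  ## one read exactly inside each bin of a single window
  anchors <- gr("chrT", 10000, 10200)
  reads <- gr("chrT", seq(9150, 10950, by = 200), seq(9160, 10960, by = 200))
  bm <- rpm_bin_matrix(reads, anchors, flank = 1000, bin_width = 200,
                       library_size = 1e6)
  expect_equal(dim(bm$matrix), c(1, 10))
  expect_equal(as.vector(bm$matrix), rep(1, 10))
  bm2 <- rpm_bin_matrix(reads, anchors, flank = 1000, bin_width = 200,
                        library_size = 2e6)
  expect_equal(bm2$matrix, bm$matrix / 2)
})

test_that("RPM matrices match brute-force overlap counting", {
  set.seed(62)
  st <- sample(0:99000, 300)
  reads <- gr("chrT", st, st + sample(30:80, 300, replace = TRUE))
  ast <- sample(20000:80000, 5)
  anchors <- gr("chrT", ast, ast + 100)
  bm <- rpm_bin_matrix(reads, anchors, flank = 2000, bin_width = 500,
                       library_size = 1e6)
  centers <- floor((ast + ast + 100) / 2)
  ## 0-based last covered base of each read
  re <- st + (GenomicRanges::end(reads) - GenomicRanges::start(reads))
  for (a in 1:5) for (b in 1:8) {
    b0 <- centers[a] - 2000 + (b - 1) * 500
    b1 <- b0 + 500
    oracle <- sum(st < b1 & re >= b0)
    expect_equal(bm$matrix[a, b], oracle, tolerance = 1e-12)
  }
})

test_that("strand-aware anchors reverse their rows; edge anchors are masked", {
  set.seed(63)
  st <- sample(0:9e4, 200)
  reads <- gr("chrT", st, st + 50)
  apos <- c(30000, 60000)
  anchors <- gr("chrT", apos, apos + 100, strand = c("+", "-"))
  fwd <- rpm_bin_matrix(reads, anchors, 2000, 500)
  rev <- rpm_bin_matrix(reads, anchors, 2000, 500, strand_aware = TRUE)
  expect_equal(rev$matrix[1, ], fwd$matrix[1, ])
  expect_equal(rev$matrix[2, ], fwd$matrix[2, 8:1])
  near_edge <- gr("chrT", 500, 600)
  bm <- rpm_bin_matrix(reads, near_edge, 2000, 500)
  expect_true(all(is.na(bm$matrix)))
  expect_equal(bm$n_masked, 1)
})

test_that("enhancer classification applies all four rules", {
  k4me1 <- gr("chrT", c(1000, 5000, 9000, 13000, 17000),
              c(1400, 5400, 9400, 13400, 17400))
  k4me3 <- gr("chrT", 9000, 9400)
  atac <- gr("chrT", c(1100, 5100, 9100, 17100), c(1200, 5200, 9200, 17200))
  k27ac <- gr("chrT", 1000, 1400)
  tss <- gr("chrT", 17600, 17601)
  calls <- classify_enhancers(k4me1, k4me3, atac, k27ac, tss, tss_pad = 1000)
  ## 1: all marks, no K4me3, has ATAC, K27ac -> active enhancer
  ## 2: K4me1+ATAC only -> enhancer, not active
  ## 3: has K4me3 -> excluded; 4: no ATAC -> excluded
  ## 5: TSS within 1 kb -> excluded
  expect_equal(calls$enhancer, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$active_enhancer, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  ## literal 1-bp pad keeps peak 5
  lit <- classify_enhancers(k4me1, k4me3, atac, k27ac, tss, tss_pad = 1)
  expect_true(lit$enhancer[5])
  ## adding K27ac never demotes, only promotes
  more <- classify_enhancers(k4me1, k4me3, atac, c(k27ac, gr("chrT", 5000,
                                                             5400)), tss)
  expect_true(all(more$enhancer == calls$enhancer))
  expect_true(all(more$active_enhancer >= calls$active_enhancer))
})

test_that("enhancer classification matches brute-force set algebra", {
  set.seed(64)
  mkset <- function(n, w) {
    s <- sample(0:2e5, n)
    gr("chrT", s, s + w)
  }
  k4me1 <- mkset(40, 400)
  k4me3 <- mkset(10, 300)
  atac <- mkset(30, 150)
  k27 <- mkset(15, 350)
  tss <- mkset(10, 1)
  calls <- classify_enhancers(k4me1, k4me3, atac, k27, tss, tss_pad = 1000)
  ov <- function(a, b) IRanges::overlapsAny(a, b)
  tssz <- GenomicRanges::resize(tss, GenomicRanges::width(tss) + 2000,
                                fix = "center")
  oracle <- !ov(k4me1, k4me3) & ov(k4me1, atac) & !ov(k4me1, tssz)
  expect_equal(calls$enhancer, oracle)
  expect_equal(calls$active_enhancer, oracle & ov(k4me1, k27))
})

test_that("differential enhancers gate on p and 3-fold change", {
  set.seed(65)
  a <- matrix(rpois(40, 100), 20, 2)
  de <- differential_enhancers(a, a, dispersion = 0)
  expect_true(all(!de$differential))
  ## 2.9-fold with small p fails the FC gate
  b <- matrix(590, 1, 2)
  a1 <- matrix(200, 1, 2)
  de29 <- differential_enhancers(a1, b, dispersion = 0)
  expect_lt(de29$p, 1e-6)
  expect_false(de29$differential)
  ## planted 5-fold set is recovered
  base <- matrix(rpois(60, 40), 30, 2)
  up <- base
  up[1:10, ] <- matrix(rpois(20, 200), 10, 2)
  de5 <- differential_enhancers(base, up, dispersion = 0)
  expect_gte(mean(de5$differential[1:10]), 0.9)
  expect_lte(mean(de5$differential[11:30]), 0.1)
})

test_that("H3K9me3 bin calls honor the inclusive 4x rule", {
  ip <- signal_track(c(40, 10, 0, 39, 4), "chrT", 25000)
  input <- signal_track(c(10, 10, 0, 10, 0), "chrT", 25000)
  pos <- h3k9me3_positive_bins(ip, input)
  ## 40/10 = 4 (inclusive), 10/10, 0/1, 39/10, 4/max(0,1)=4
  expect_equal(pos$positive, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  ## IP = 4x input -> every covered bin positive (boundary inclusive)
  ip4 <- signal_track(4 * input$values, "chrT", 25000)
  expect_equal(h3k9me3_positive_bins(ip4, input)$positive,
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  ## IP = input -> none positive
  expect_true(all(!h3k9me3_positive_bins(input, input)$positive))
})

test_that("differential H3K9me3 bins are symmetric under stage swap", {
  set.seed(66)
  ia <- signal_track(rpois(50, 20), "chrT", 25000)
  na <- signal_track(rpois(50, 10), "chrT", 25000)
  ib <- signal_track(rpois(50, 20), "chrT", 25000)
  nb <- signal_track(rpois(50, 10), "chrT", 25000)
  ab <- h3k9me3_differential_bins(ia, na, ib, nb)
  ba <- h3k9me3_differential_bins(ib, nb, ia, na)
  expect_equal(ab$gained, ba$lost)
  expect_equal(ab$lost, ba$gained)
  ## brute-force ratio check
  ra <- ia$values / pmax(na$values, 1)
  rb <- ib$values / pmax(nb$values, 1)
  expect_equal(ab$gained, rb >= 4 * pmax(ra, .Machine$double.eps) & rb > 0)
})

test_that("expression-in-loop assignment uses gene midpoints", {
  loops <- pixel_loops(c(10, 50), c(30, 80), 1e4)
  genes <- gr("chrT", c(150000, 250000, 600000, 205000),
              c(160000, 260000, 610000, 215000))
  genes$gene_id <- c("g1", "g2", "g3", "g4")
  tpm <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    H9 = c(3, 5, 5, 2), DE = c(7, 5, 5, 2))
  res <- expression_in_loops(loops, genes, tpm, "DE", "H9")
  ## loop 1 spans 100 kb..310 kb: g1, g2, g4 inside; loop 2: 500..810 kb: g3
  expect_equal(sort(res$gene_loop$gene_id), c("g1", "g2", "g3", "g4"))
  got <- res$log2fc[res$gene_loop$gene_id == "g1"]
  expect_equal(got, log2(8 / 4))  # TPM 3 -> 7 gives exactly 1
  expect_equal(got, 1)
  ## all-equal TPM -> all zero
  res0 <- expression_in_loops(loops, genes, tpm, "H9", "H9")
  expect_true(all(res0$log2fc == 0))
})

test_that("expression-in-loop containment matches a brute-force oracle", {
  set.seed(67)
  loops <- pixel_loops(sample(10:100, 10), sample(150:300, 10), 1e4)
  gs <- sample(0:3e6, 50)
  genes <- gr("chrT", gs, gs + 5000)
  genes$gene_id <- paste0("g", 1:50)
  tpm <- data.frame(gene_id = genes$gene_id,
                    A = runif(50, 0, 50), B = runif(50, 0, 50))
  res <- expression_in_loops(loops, genes, tpm, "B", "A")
  gmid <- gs + 2500
  n_inside_loops <- 0
  for (i in 1:10) {
    inside <- which(gmid >= loops$start1[i] & gmid < loops$end2[i])
    hits <- res$gene_loop$gene_id[res$gene_loop$loop == i]
    expect_equal(sort(hits), sort(genes$gene_id[inside]))
    if (!length(inside)) n_inside_loops <- n_inside_loops + 1
  }
  expect_equal(res$n_loops_without_genes, n_inside_loops)
})
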