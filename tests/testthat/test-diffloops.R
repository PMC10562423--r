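test_that("merging collapses duplicates and keeps provenance", {
  bs <- 1e4
  l1 <- pixel_loops(c(10, 50), c(40, 90), bs)
  l2 <- pixel_loops(10, 40, bs)
  l3 <- pixel_loops(c(10, 70), c(40, 120), bs)
  u <- merge_loop_calls(list(A = l1, B = l2, C = l3), merge_resolution = bs)
  expect_equal(nrow(u), 3)
  shared <- u[loop_anchor_bins(u, bs)$bin1 == 10, ]
  expect_equal(shared$stages, "A,B,C")
  expect_equal(shared$n_stages, 3)
  ## disjoint sets add up
  d1 <- pixel_loops(c(10, 20), c(40, 60), bs)
  d2 <- pixel_loops(c(100, 120), c(140, 160), bs)
  expect_equal(nrow(merge_loop_calls(list(A = d1, B = d2), bs)), 4)
})

test_that("jittered near-duplicates cluster like all-pairs transitive closure", {
  set.seed(41)
  bs <- 1e4
  for (rep in 1:5) {
    base1 <- sample(20:400, 25)
    base2 <- base1 + sample(15:60, 25, replace = TRUE)
    j1 <- base1 + sample(-1:1, 25, replace = TRUE)
    j2 <- base2 + sample(-1:1, 25, replace = TRUE)
    la <- pixel_loops(base1, base2, bs)
    lb <- pixel_loops(j1, j2, bs)
    u <- merge_loop_calls(list(s1 = la, s2 = lb), merge_resolution = bs)
    ## oracle: union-find over the all-pairs "within 1 bin both anchors" graph
    allb1 <- c(base1, j1); allb2 <- c(base2, j2)
    n <- length(allb1)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(allb1[i] - allb1[j]) <= 1 && abs(allb2[i] - allb2[j]) <= 1 &&
            comp[j] != comp[i]) {
          comp[comp == comp[max(i, j)]] <- comp[min(i, j)]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    expect_equal(nrow(u), length(unique(comp)))
  }
})

test_that("loop quantification sums the pixel neighborhood", {
  n <- 50
  cm <- contact_matrix(25, 40, 40, n, "chrT", 1e4)
  u <- pixel_loops(25, 40)
  lc0 <- quantify_loops(u, list(S = list(cm)), radius = 0)
  expect_equal(as.vector(lc0$counts), 40)
  ## radius 1 equals a brute 3x3 window sum on a random matrix
  rcm <- random_cm(50, seed = 42)
  dense <- cm_dense(rcm)
  u2 <- pixel_loops(c(12, 30), c(30, 44))
  lc1 <- quantify_loops(u2, list(S = list(rcm)), radius = 1)
  oracle <- c(sum(dense[12:14, 30:32]), sum(dense[30:32, 44:46]))
  expect_equal(as.vector(lc1$counts), oracle)
  ## empty matrix -> zero everywhere
  empty <- contact_matrix(integer(0), integer(0), numeric(0), n, "chrT", 1e4)
  lce <- quantify_loops(u2, list(S = list(empty)), radius = 1)
  expect_equal(as.vector(lce$counts), c(0, 0))
})

test_that("loops outside the matrix are flagged missing", {
  cm <- random_cm(50, seed = 43)
  u <- pixel_loops(c(0, 48), c(10, 49))
  lc <- quantify_loops(u, list(S = list(cm)), radius = 1)
  expect_true(all(is.na(lc$counts)))
})

test_that("exact NB test honors its closed forms", {
  ## maximal symmetry -> p = 1
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), 0), 1)
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), 0.5), 1)
  ## one-sided extreme: 0 vs 20 under the conditional binomial
  expect_equal(nb_exact_test(c(0, 0), c(12, 8), 0), 2 * 0.5^20)
  ## all-zero counts
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.3), 1)
})

test_that("exact NB test matches brute-force enumeration", {
  set.seed(44)
  for (rep in 1:40) {
    sa <- rpois(1, 8); sb <- rpois(1, 8)
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    expect_equal(nb_exact_test(sa, sb, 0),
                 brute_nb_p(sa, sb, 1, 1, 0), tolerance = 1e-10)
    phi <- runif(1, 0.05, 0.6)
    a <- rpois(na, 6); b <- rpois(nb, 6)
    expect_equal(nb_exact_test(a, b, phi),
                 brute_nb_p(sum(a), sum(b), na, nb, phi), tolerance = 1e-10)
  }
})

test_that("exact NB test agrees with edgeR's exact test", {
  skip_if_not_installed("edgeR")
  set.seed(45)
  phi <- 0.1
  n <- 40
  a <- matrix(rnbinom(2 * n, mu = 20, size = 1 / phi), n, 2)
  b <- matrix(rnbinom(2 * n, mu = 30, size = 1 / phi), n, 2)
  mine <- vapply(seq_len(n), function(i) nb_exact_test(a[i, ], b[i, ], phi), 0)
  y <- edgeR::DGEList(counts = cbind(a, b), group = c(1, 1, 2, 2))
  y$samples$lib.size <- rep(mean(colSums(cbind(a, b))), 4)
  theirs <- edgeR::exactTest(y, dispersion = phi)$table$PValue
  expect_equal(mine, theirs, tolerance = 1e-8)
})

test_that("dispersion estimation recovers method-of-moments truth", {
  set.seed(46)
  phi <- 0.2
  counts <- array(rnbinom(3000 * 2 * 4, mu = 50, size = 1 / phi),
                  dim = c(3000, 2, 4))
  est <- estimate_dispersion(counts)
  expect_lt(abs(est - phi), 0.04)
  ## Poisson data -> ~0
  pois <- array(rpois(3000 * 2 * 4, 50), dim = c(3000, 2, 4))
  expect_lt(estimate_dispersion(pois), 0.01)
  ## single replicate is refused
  expect_error(estimate_dispersion(array(1, c(5, 2, 1))), "single replicate")
})

test_that("differential calling gates on p, FDR and fold change together", {
  stages <- c("H9", "DE")
  mk_lc <- function(counts) {
    structure(list(counts = counts,
                   normalized = array(NA_real_, dim(counts)),
                   loops = pixel_loops(seq_len(dim(counts)[1]) * 10,
                                       seq_len(dim(counts)[1]) * 10 + 30),
                   stages = stages, radius = 1),
              class = "loop_counts")
  }
  ## identical counts -> all common
  same <- array(rep(20, 10 * 2 * 2), dim = c(10, 2, 2))
  ld <- call_differential(mk_lc(same), dispersion = 0)
  expect_true(all(ld$result$label == "common"))
  ## planted 8-fold jump at mean 40 vs 5 -> differential
  counts <- array(15, dim = c(20, 2, 2))
  counts[1, 1, ] <- c(5, 5); counts[1, 2, ] <- c(40, 40)
  ld <- call_differential(mk_lc(counts), dispersion = 0)
  expect_equal(ld$result$label[1], "differential")
  expect_true(all(ld$result$label[-1] == "common"))
  ## 3.9-fold with a tiny p-value still fails the FC gate
  c39 <- array(400, dim = c(20, 2, 2))
  c39[1, 1, ] <- 400; c39[1, 2, ] <- round(3.85 * 400)
  ld39 <- call_differential(mk_lc(c39), dispersion = 0)
  expect_lt(ld39$p[1, 1], 1e-10)
  expect_lt(ld39$result$fc_max[1], 4)
  expect_equal(ld39$result$label[1], "common")
})

test_that("differential and common labels partition the union", {
  set.seed(47)
  counts <- array(rpois(60 * 3 * 2, 30), dim = c(60, 3, 2),
                  dimnames = list(NULL, c("A", "B", "C"), NULL))
  lc <- structure(list(counts = counts, normalized = array(NA_real_, dim(counts)),
                       loops = pixel_loops(1:60 * 5, 1:60 * 5 + 40),
                       stages = c("A", "B", "C"), radius = 1),
                  class = "loop_counts")
  ld <- call_differential(lc)
  expect_equal(sort(unique(ld$result$label)), sort(unique(c("common",
    ld$result$label))))
  expect_equal(sum(ld$result$label %in% c("differential", "common")), 60)
})

test_that("stage assignment follows the max/min rule with earliest-tie", {
  stages <- c("H9", "DE", "PGT", "PP", "SCb")
  mk_ld <- function(profiles) {
    nL <- nrow(profiles)
    structure(list(
      result = data.frame(label = rep("differential", nL)),
      stages = stages,
      counts = array(1, c(nL, 5, 2)),
      normalized = array(rep(profiles, 2), c(nL, 5, 2))),
      class = "loop_diff")
  }
  prof <- rbind(c(0.1, 0.9, 0.2, 0.1, 0.1),
                c(0.9, 0.8, 0.2, 0.2, 0.2))
  ld <- assign_stage(mk_ld(prof))
  expect_equal(ld$result$direction, c("gained", "lost"))
  expect_equal(ld$result$assigned_stage, c("DE", "PGT"))
  expect_true(ld$result$tie[2])   # minimum shared by PGT/PP/SCb
  expect_false(ld$result$tie[1])
})

test_that("stage assignment matches an argmax/argmin oracle on random profiles", {
  set.seed(48)
  stages <- c("H9", "DE", "PGT", "PP", "SCb")
  profiles <- matrix(runif(40 * 5), 40, 5)
  ld <- structure(list(
    result = data.frame(label = rep("differential", 40)),
    stages = stages,
    counts = array(1, c(40, 5, 2)),
    normalized = array(rep(profiles, 2), c(40, 5, 2))),
    class = "loop_diff")
  ld <- assign_stage(ld)
  for (i in 1:40) {
    deltas <- diff(profiles[i, ])
    gained <- deltas[which.max(abs(deltas))] > 0
    expect_equal(ld$result$direction[i], if (gained) "gained" else "lost")
    expect_equal(ld$result$assigned_stage[i],
                 stages[if (gained) which.max(profiles[i, ])
                        else which.min(profiles[i, ])])
  }
})

test_that("loop_diff objects print a coherent summary", {
  set.seed(49)
  counts <- array(rpois(30 * 2 * 2, 25), dim = c(30, 2, 2),
                  dimnames = list(NULL, c("A", "B"), NULL))
  counts[1, 2, ] <- counts[1, 2, ] + 200
  lc <- structure(list(counts = counts, normalized = array(NA_real_, dim(counts)),
                       loops = pixel_loops(1:30 * 5, 1:30 * 5 + 40),
                       stages = c("A", "B"), radius = 1),
                  class = "loop_counts")
  ld <- assign_stage(call_differential(lc, dispersion = 0))
  expect_output(print(ld), "differential: 1")
  s <- summary(ld)
  expect_equal(s$n_differential, 1)
  expect_output(print(s), "loops: 30")
})
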