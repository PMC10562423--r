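#' Configuration for the synthetic multi-stage Hi-C generator
#'
#' The generator emulates the structure the loop pipeline assumes: power-law
#' distance decay, a compartment checkerboard, and planted loops whose
#' strength varies across an ordered stage panel, with Poisson counting
#' noise and replicate-level depth jitter. Defaults describe one 20-Mb toy
#' chromosome at 10-kb bins, five stages (H9, DE, PGT, PP, SCb) with two
#' replicates at ~2e6 contacts each.
#'
#' @param n_bins bins on the toy chromosome.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @param stages ordered stage names.
#' @param replicates replicates per stage.
#' @param depth target contacts per replicate (jittered +/-10% per
#'   replicate).
#' @param alpha distance-decay exponent: mean contact ~ (d+1)^(-alpha).
#' @param kappa compartment checkerboard multiplier: same-compartment pixels
#'   scaled by (1+kappa), cross-compartment by (1-kappa).
#' @param block_bins compartment block width in bins (alternating signs).
#' @param loop_multiplier strength of planted stage-specific loops (fold
#'   excess over background at the loop pixel neighborhood).
#' @param common_multiplier strength of planted constitutive loops.
#' @param persistence after a gained loop's peak stage (resp. before a lost
#'   loop's trough) the multiplier relaxes to `1 + persistence *
#'   (loop_multiplier - 1)`, modelling partial persistence so that the
#'   extreme stage stays unique.
#' @param n_common,n_gained_per_stage,n_lost_per_stage planted loop counts;
#'   gained/lost loops are planted at stages 2..S (a change needs a prior
#'   stage).
#' @param n_null additional candidate loops with multiplier 1 (background
#'   positions treated as loop calls, exercising specificity).
#' @param min_loop_bins,max_loop_bins planted loop span range in bins
#'   (minimum respects the 6-bin loop-caller distance floor).
#' @param seed integer seed; all outputs are pure functions of the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_bins = 2000, bin_size = 10000, chrom = "chrS",
                       stages = c("H9", "DE", "PGT", "PP", "SCb"),
                       replicates = 2, depth = 2e6, alpha = 1,
                       kappa = 0.3, block_bins = 50,
                       loop_multiplier = 6, common_multiplier = 3,
                       persistence = 0.3,
                       n_common = 40, n_gained_per_stage = 10,
                       n_lost_per_stage = 5, n_null = 40,
                       min_loop_bins = 20, max_loop_bins = 80,
                       seed = 1) {
  stopifnot(n_bins >= 100, bin_size > 0, length(stages) >= 2,
            replicates >= 1, alpha > 0, kappa >= 0, kappa < 1,
            loop_multiplier >= 1, common_multiplier >= 1,
            min_loop_bins >= 6, max_loop_bins > min_loop_bins)
  structure(as.list(environment()), class = "sim_config")
}

## Upper-triangle pixel index vectors (0-based bins, j >= i).
ut_pixels <- function(n) {
  i <- rep.int(0:(n - 1), n:1)
  j <- i + sequence(n:1) - 1L
  list(i = i, j = j)
}

## Linear position of pixel (i, j), j >= i, in the ut_pixels ordering.
ut_pos <- function(i, j, n) {
  i * n - i * (i - 1) / 2 + (j - i) + 1
}

## Compartment sign vector: alternating +1/-1 blocks.
compartment_plan <- function(n_bins, block_bins) {
  rep_len(rep(c(1, -1), each = block_bins), n_bins)
}

## Gaussian taper over the 3x3 loop-pixel neighborhood, normalized so the
## neighborhood mean of the excess equals the nominal multiplier.
loop_taper_weights <- function(sigma = 0.8) {
  off <- expand.grid(di = -1:1, dj = -1:1)
  w <- exp(-(off$di^2 + off$dj^2) / (2 * sigma^2))
  cbind(off, w = w / mean(w))
}

## Place planted loops: pixel positions away from edges and each other.
place_loops <- function(config) {
  S <- length(config$stages)
  n_change <- (S - 1) * (config$n_gained_per_stage + config$n_lost_per_stage)
  n_total <- config$n_common + n_change + config$n_null
  margin <- 15
  taken_i <- numeric(0); taken_j <- numeric(0)
  bin1 <- bin2 <- integer(n_total)
  k <- 0; tries <- 0
  while (k < n_total) {
    tries <- tries + 1
    if (tries > 100 * n_total) stop("cannot place planted loops; too dense")
    d <- sample(config$min_loop_bins:config$max_loop_bins, 1)
    i <- sample(margin:(config$n_bins - 1 - margin - d), 1)
    j <- i + d
    if (length(taken_i) &&
        any(abs(taken_i - i) <= 4 & abs(taken_j - j) <= 4)) next
    k <- k + 1
    bin1[k] <- i; bin2[k] <- j
    taken_i <- c(taken_i, i); taken_j <- c(taken_j, j)
  }
  data.frame(bin1 = bin1, bin2 = bin2)
}

## Per-stage multiplier profiles and truth labels for the planted loops.
plant_truth <- function(config, placed) {
  S <- length(config$stages)
  m <- config$loop_multiplier
  relax <- 1 + config$persistence * (m - 1)
  rows <- list()
  add <- function(label, stage_idx, prof) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label,
      stage = if (is.na(stage_idx)) NA_character_ else
        config$stages[stage_idx],
      t(prof))
  }
  for (k in seq_len(config$n_common)) add("common", NA, rep(config$common_multiplier, S))
  for (s in 2:S) {
    for (k in seq_len(config$n_gained_per_stage)) {
      prof <- rep(1, S)
      prof[s] <- m
      if (s < S) prof[(s + 1):S] <- relax
      add("gained", s, prof)
    }
    for (k in seq_len(config$n_lost_per_stage)) {
      prof <- rep(m, S)
      prof[s] <- 1
      if (s < S) prof[(s + 1):S] <- relax
      add("lost", s, prof)
    }
  }
  for (k in seq_len(config$n_null)) add("null", NA, rep(1, S))
  if (!length(rows)) {
    truth <- data.frame(bin1 = integer(0), bin2 = integer(0),
                        label = character(0), stage = character(0))
    for (s in config$stages) truth[[paste0("mult_", s)]] <- numeric(0)
    return(truth)
  }
  truth <- do.call(rbind, rows)
  names(truth)[-(1:2)] <- paste0("mult_", config$stages)
  cbind(placed[seq_len(nrow(truth)), , drop = FALSE], truth)
}

#' Simulate multi-stage Hi-C contact matrices with planted truth
#'
#' Pixel means follow `depth_scale * (d+1)^(-alpha) * (1 + kappa v_i v_j) *
#' L(i,j,stage)` where `v` is the alternating compartment plan and `L` the
#' Gaussian-tapered planted loop multiplier on each loop pixel's 3x3
#' neighborhood; counts are Poisson, with replicate depths jittered +/-10%.
#'
#' @param config a `sim_config`.
#' @return list: `matrices` (named list stage -> list of replicate
#'   `contact_matrix`), `truth` (planted-loop table with per-stage
#'   multipliers, labels and pixel bins), `compartments` (per-bin sign),
#'   `config`.
#' @export
simulate_stage_hic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_bins
  S <- length(config$stages)
  px <- ut_pixels(n)
  d <- px$j - px$i
  v <- compartment_plan(n, config$block_bins)
  base <- (d + 1)^(-config$alpha) *
    (1 + config$kappa * v[px$i + 1L] * v[px$j + 1L])
  scale0 <- config$depth / sum(base)
  placed <- place_loops(config)
  truth <- plant_truth(config, placed)
  tw <- loop_taper_weights()
  mult_cols <- paste0("mult_", config$stages)
  ## per-stage loop factor on the affected pixels
  loop_pos <- lapply(seq_len(nrow(truth)), function(k) {
    ii <- truth$bin1[k] + tw$di
    jj <- truth$bin2[k] + tw$dj
    ut_pos(pmin(ii, jj), pmax(ii, jj), n)
  })
  matrices <- stats::setNames(vector("list", S), config$stages)
  for (s in seq_len(S)) {
    mu_s <- base
    for (k in seq_len(nrow(truth))) {
      m_ks <- truth[[mult_cols[s]]][k]
      if (m_ks != 1)
        mu_s[loop_pos[[k]]] <- mu_s[loop_pos[[k]]] *
          (1 + (m_ks - 1) * tw$w)
    }
    matrices[[s]] <- lapply(seq_len(config$replicates), function(r) {
      jitter <- stats::runif(1, 0.9, 1.1)
      counts <- stats::rpois(length(mu_s), mu_s * scale0 * jitter)
      if (sum(counts) == 0)
        warning("simulated library is empty (achieved total 0); ",
                "depth too low")
      nz <- counts > 0
      contact_matrix(px$i[nz], px$j[nz], counts[nz], n, config$chrom,
                     config$bin_size)
    })
  }
  list(matrices = matrices, truth = truth, compartments = v, config = config)
}

#' Simulate peak sets and tracks consistent with the planted loops
#'
#' Places CTCF and RAD21 peaks at the anchors of loops active at each stage
#' (plus a configurable fraction of pre-bound CTCF sites at anchors of loops
#' that only form later), NIPBL/RAD21 co-occupied sites at a fixed
#' fractional position inside gained loops, planted enhancer mark
#' combinations with known truth classes, and 25-kb H3K9me3 IP/input tracks
#' with domains over gained-loop anchors at the stages before the loop
#' forms.
#'
#' @param sim output of [simulate_stage_hic()].
#' @param peak_halfwidth peak half-width in bp.
#' @param internal_site_frac fractional position of the internal
#'   NIPBL/RAD21 site within gained loops.
#' @param prebound_frac fraction of future anchors already CTCF-bound at
#'   earlier stages.
#' @param n_enhancers planted enhancer-locus count (cycled over truth
#'   classes).
#' @return list: `peaks` (stage -> named list of `GRanges`), `sites`
#'   (NIPBL/RAD21 internal sites per stage), `enhancers` (peak sets +
#'   `truth`), `k9` (stage -> list(ip, input) 25-kb `signal_track`s).
#' @export
simulate_peaks_and_tracks <- function(sim, peak_halfwidth = 200,
                                      internal_site_frac = 0.3,
                                      prebound_frac = 0.5,
                                      n_enhancers = 40) {
  config <- sim$config
  set.seed(config$seed + 1L)
  truth <- sim$truth
  S <- length(config$stages)
  bs <- config$bin_size
  chrom <- config$chrom
  mult_cols <- paste0("mult_", config$stages)
  anchor_mid <- function(bin) bin * bs + bs / 2
  mk_peaks <- function(mids) {
    if (!length(mids)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = pmax(1, round(mids - peak_halfwidth) + 1),
                       end = round(mids + peak_halfwidth)))
  }
  prebound <- stats::runif(nrow(truth)) < prebound_frac
  peaks <- list()
  sites <- list()
  for (s in seq_len(S)) {
    active <- truth[[mult_cols[s]]] > 1
    future <- !active & truth$label %in% c("gained", "lost") & prebound
    amids <- c(anchor_mid(truth$bin1[active]), anchor_mid(truth$bin2[active]))
    pmids <- c(anchor_mid(truth$bin1[future]), anchor_mid(truth$bin2[future]))
    peaks[[config$stages[s]]] <- list(
      CTCF = mk_peaks(c(amids, pmids)),
      RAD21 = mk_peaks(amids))
    gained_here <- truth$label == "gained" & active
    site_mids <- anchor_mid(truth$bin1[gained_here]) +
      internal_site_frac * (anchor_mid(truth$bin2[gained_here]) -
                              anchor_mid(truth$bin1[gained_here]))
    sites[[config$stages[s]]] <- list(
      NIPBL = mk_peaks(site_mids), RAD21 = mk_peaks(site_mids))
  }
  ## enhancer truth: cycle combinations over spaced loci
  classes <- c("active_enhancer", "enhancer", "has_k4me3", "no_atac",
               "tss_proximal")
  span <- config$n_bins * bs
  loci <- round(seq(span * 0.05, span * 0.95, length.out = n_enhancers))
  cls <- rep_len(classes, n_enhancers)
  loc_gr <- mk_peaks(loci)
  enh <- list(
    H3K4me1 = loc_gr,
    H3K4me3 = loc_gr[cls == "has_k4me3"],
    ATAC_TF = loc_gr[cls != "no_atac"],
    H3K27ac = loc_gr[cls == "active_enhancer"],
    TSS = GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = loci[cls == "tss_proximal"] + 1, width = 1)),
    truth = data.frame(locus = loci, class = cls,
                       enhancer = cls %in% c("active_enhancer", "enhancer"),
                       active = cls == "active_enhancer"))
  ## H3K9me3 at 25-kb bins: domains over gained-loop anchors pre-formation
  n25 <- as.integer(ceiling(span / 25000))
  k9 <- list()
  for (s in seq_len(S)) {
    ip <- rep(10, n25)
    for (k in which(truth$label == "gained")) {
      s_star <- match(truth$stage[k], config$stages)
      if (s < s_star) {
        b <- unique(coord_to_bin(
          c(anchor_mid(truth$bin1[k]), anchor_mid(truth$bin2[k])), 25000))
        ip[b + 1L] <- 80
      }
    }
    k9[[config$stages[s]]] <- list(
      ip = signal_track(ip, chrom, 25000),
      input = signal_track(rep(10, n25), chrom, 25000))
  }
  list(peaks = peaks, sites = sites, enhancers = enh, k9 = k9)
}

## Truncated-normal sampler (rejection).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate an ATAC fragment table with a two-component size mixture
#'
#' True insert sizes are drawn from truncated normals — sub-nucleosomal
#' (TF) N(82, 15) on \[30, 140\] and mono-nucleosomal N(205, 20) on
#' \[150, 280\] — and raw coordinates are widened by the 9-bp Tn5
#' duplication (start - 4, end + 5) that [shift_and_partition_atac()]
#' removes.
#'
#' @param n_tf,n_nuc fragment counts per component.
#' @param sites center positions (bp) fragments are scattered around.
#' @param chrom chromosome name.
#' @param jitter max distance (bp) of a fragment center from its site.
#' @param seed integer seed.
#' @return list: `fragments` (chrom/start/end/strand data.frame), `truth`
#'   (component per row).
#' @export
simulate_atac_fragments <- function(n_tf, n_nuc, sites = c(5e4, 1e5),
                                    chrom = "chrS", jitter = 200,
                                    seed = 1) {
  set.seed(seed)
  n <- n_tf + n_nuc
  if (n == 0)
    return(list(fragments = data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0)),
                truth = character(0)))
  len <- c(if (n_tf) round(rtrunc_norm(n_tf, 82, 15, 30, 140)),
           if (n_nuc) round(rtrunc_norm(n_nuc, 205, 20, 150, 280)))
  truth <- rep(c("tf", "nuc"), c(n_tf, n_nuc))
  center <- sample(sites, n, replace = TRUE) +
    round(stats::runif(n, -jitter, jitter))
  true_start <- round(center - len / 2)
  frag <- data.frame(chrom = chrom,
                     start = true_start - 4L,
                     end = true_start + len + 5L,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  list(fragments = frag, truth = truth)
}
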