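---
title: "Stage-resolved CTCF loop dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved CTCF loop dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a stepwise differentiation (here modelled after the pancreatic
lineage: hESC H9 → definitive endoderm → primitive gut tube → pancreatic
progenitor → islet organoid, abbreviated H9, DE, PGT, PP, SC-β), chromatin
loops anchored at CTCF/cohesin sites are formed and disassembled
stage-by-stage. `loopshift` implements the quantitative pipeline for
detecting these dynamics from binned contact matrices (Hi-C or
HiChIP-style), assigning each dynamic loop to the stage where it peaks or
bottoms, classifying *how* new loops arise at the anchor level, and relating
loops to 1-D chromatin tracks (ChIP peaks, ATAC fragments, expression).

Because the statistics involved (aggregate scores, exact count tests,
permutation tests) are easy to get subtly wrong, the package ships a
synthetic multi-stage generator with planted ground truth; every stage of
the pipeline is exercised end-to-end against that truth.

## Contact-map normalization

Working per chromosome with bins of width $b$ (5–25 kb; loops at 10 kb,
compartments at 25 kb):

* **Depth matching.** Libraries being compared are subsampled without
  replacement to the total of the smallest one (`subsample_contacts()`),
  so count tests can assume equal library size.
* **Balancing.** Knight–Ruiz (KR) balancing finds a scaling vector $v$ with
  $v_i v_j O_{ij}$ having equal row sums; the implementation is the standard
  inner–outer Newton iteration with a conjugate-gradient inner solve, with
  iterative correction (repeated division by the square root of row sums) as
  a fallback when the Newton scheme stalls — both converge to the same
  doubly-balanced fixed point on strictly positive matrices. Convergence is
  declared at a relative row-sum spread ≤ 1e-6 within 3000 iterations; bins
  with zero marginal are masked beforehand. Vanilla-coverage-sqrt (VCsqrt)
  balancing divides each entry by $\sqrt{r_i r_j}$ of the raw marginals and
  is used for HiChIP-style maps.
* **Distance normalization.** The expected value $E(d)$ is the mean contact
  at separation $d$ over unmasked pixels of the same chromosome. Two forms
  are provided: the residual form $(O - E)/(E + 1)$, which centers
  background on 0 and is used for differential quantification, and the
  classic ratio $O/E$, which centers background on 1 and is used for
  aggregate (APA) stacks, where a ratio-of-positives score is taken.
* **Compartments.** The A/B eigenvector is the leading eigenvector of the
  Pearson correlation matrix of the distance-normalized map at 25 kb; signs
  are oriented against a user-supplied active-chromatin track when given,
  otherwise fixed deterministically. Constant or empty rows are masked, not
  zero-filled.

## Aggregate loop scores

APA stacks collect, for each loop, the $(2f+1)^2$ pixel window (default
$f = 10$, i.e. 210 kb × 210 kb at 10 kb) of the normalized map centered on
the loop pixel — the bin pair containing the two anchor midpoints — and
aggregate per pixel with the median (mean available). Windows crossing the
diagonal or the chromosome edge are dropped and counted. Orientation
contract: rows index the 5′ anchor, columns the 3′ anchor, both increasing
with genomic coordinate, so "lower-right" lies downstream on both axes and
"top-right" crosses over the loop.

* `apa_score()`: center pixel over the mean of the 5×5 lower-right corner
  block (the alternative lower-left corner is available behind a flag).
* `meta_score()`: center over the median of the 2×2 top-right block.
* `corner_categories()`: condition differences of mean signal in the 5×5
  top-left (category 1, inside–outside left), bottom-right (category 2,
  inside–outside right) and top-right (category 3, crossing) corners.
* `scaled_multi_anchor_metaplot()`: each loop's inter-anchor span is
  rescaled to 10 equal bins by length-weighted pixel averaging on both axes
  (fixed unscaled flanks), the per-loop comparison (subtraction or log2
  fold change, non-positive pixels floored at 1e-6) is computed first, and
  the per-pixel median across loops is the summary. Spans shorter than 10
  source bins are dropped and counted.

## Differential and stage-specific loops

The four-step pipeline (`merge_loop_calls()` → `quantify_loops()` →
`call_differential()` → `assign_stage()`):

1. Candidate loops from all stages are merged; loops whose anchor-center
   bins agree within one bin (transitively) collapse to the earliest-stage
   record, with provenance retained.
2. Each union loop is quantified in every stage × replicate as the raw
   subsampled count summed over the 3×3 pixel neighborhood (radius 1 bin by
   default, absorbing anchor jitter; radius 0 available), plus the
   KR + distance-normalized mean over the same neighborhood.
3. For every stage pair, replicate-summed counts are compared with a
   two-sided **exact negative-binomial test**: conditional on the grand
   total, the group total follows a negative hypergeometric
   (beta-binomial) law with common dispersion $\phi$, reducing to the
   conditional binomial at $\phi = 0$; the p-value is the doubled smaller
   tail. $\phi$ defaults to a pooled method-of-moments estimate across
   loops ($\hat\phi = \sum(s^2 - \bar x)/\sum \bar x^2$, floored at 0);
   with a single replicate it must be supplied. The test is numerically
   identical to edgeR's exact test at equal library sizes (verified in the
   test suite), but is pluggable so an external edgeR run can be swapped in.
4. A loop is **differential** when any stage pair passes p < 0.05,
   BH-FDR < 0.1 (computed across loops within each pair) and fold change
   ≥ 4 in either direction; all others are **common**. The fold-change gate
   is computed on group mean counts with a pseudocount of 0.5 — counts are
   the scale on which a 4-fold gate is meaningful, while the normalized
   residuals (centered on 0) would compress any ratio toward 1.
   Differential loops are then directed by the sign of the
   largest-magnitude consecutive-stage change of their mean normalized
   frequency profile: **gained** loops are assigned to the stage of maximum
   frequency, **lost** loops to the stage of minimum; exact ties go to the
   earliest developmental stage and are flagged.

## Anchor-level annotation

* `annotate_occupancy()`: an anchor padded by ±5 kb is occupied if it
  intersects ≥ 1 peak; loops are classed `both`/`one`/`none` per factor.
* `shuffle_overlap_test()`: peaks are relocated uniformly within their own
  chromosome (lengths preserved, overlaps allowed — chromosome-level peak
  density is the dominant confounder and is preserved). Two p-values are
  reported: the literal depletion-style count of shuffles beating the
  observed ratio divided by the shuffle number, and the standard add-one
  enrichment p-value $(1 + \#\{\text{shuffled} \ge \text{obs}\})/(n+1)$.
  The add-one form is valid (super-uniform) by construction; calibration
  checks therefore test one-sidedly for anti-conservatism.
* `classify_anchor_change()`: a loop new at stage $t$ is
  `both_anchors_new` when neither anchor matches (within 1 bin,
  configurable) any anchor of a stage-$t{-}1$ loop; `extension_one_anchor`
  when exactly one anchor is shared and the new partner lies strictly
  outside the prior span on the far side of the shared anchor;
  `paired_new_anchor_split` when the new partner lies strictly inside the
  prior span; `other` otherwise (e.g. two reused anchors in a new pairing).
  The categories are exhaustive and mutually exclusive.
* `rank_by_internal_site()`: co-occupied sites (intersection of e.g. NIPBL
  and RAD21 peaks) strictly inside the loop span are mapped to a scaled
  [0, 1] coordinate between anchor midpoints; with several internal sites
  the one nearest the left anchor is used and the multiplicity reported.

## Track-level analyses

* **ATAC**: fragment starts are shifted +4 bp and ends −5 bp (the − strand
  read's 5′ end is the fragment end), removing the 9-bp Tn5 duplication;
  shifted inserts of 50–115 bp are sub-nucleosomal (ATAC-TF) and
  180–247 bp mono-nucleosomal (ATAC-Nuc), both gates inclusive.
* **RPM matrices**: anchors × bins read counts divided by library size in
  millions; minus-strand anchors can be flipped; edge anchors are masked.
* **Enhancers**: H3K4me1 peaks without H3K4me3, overlapping an ATAC-TF
  peak and clear of TSS ± pad; those with H3K27ac are additionally active.
  The TSS pad defaults to 1000 bp — a ±1 bp exclusion would exclude
  essentially nothing and defeat the rule's promoter-filtering purpose —
  but a literal ±1 bp remains selectable.
* **H3K9me3**: on 25-kb bins of depth-normalized IP and input tracks, a
  bin is positive when IP/input ≥ 4 (boundary inclusive); the input is
  floored at one read per bin, which both prevents division by zero and
  keeps the boundary rule exact (an additive pseudocount would make
  IP = 4 × input fall strictly below 4). Differential bins change ≥ 4-fold
  between stages, symmetrically.
* **Expression in loops**: genes whose body midpoint falls inside a loop
  span contribute $\log_2((\mathrm{TPM}_t + 1)/(\mathrm{TPM}_{t-1} + 1))$
  to that loop set's distribution.

## The synthetic generator

`simulate_stage_hic()` draws Poisson counts with pixel means
$$\mu_{ij} = c \,(d+1)^{-\alpha}\,(1 + \kappa\, v_i v_j)\, L_{ij},$$
where $d = |i-j|$, $\alpha = 1$ is the decay exponent, $v \in \{\pm 1\}$ an
alternating compartment block plan with multiplier $\kappa = 0.3$, and $L$
the planted loop factor. Defaults describe one 20-Mb chromosome at 10-kb
bins, five stages × two replicates at ~2×10⁶ contacts each with ±10% depth
jitter per replicate — minutes on one CPU. Loop excess is spread over the
3×3 pixel neighborhood with a Gaussian taper (σ = 0.8 bins) whose weights
are normalized so the neighborhood mean of $L$ equals the nominal
multiplier: a planted 6× loop yields a 6-fold excess in the radius-1
quantification that the pipeline actually uses, keeping the planted effect
size and the detection gate on the same scale.

Planted profiles: constitutive loops at multiplier 3 in all stages; gained
loops at stages 2..S jump from 1 to the multiplier (default 6) at their
stage and relax to $1 + 0.3\,(m-1)$ afterwards (partial persistence keeps
the peak stage unique); lost loops mirror this; additional multiplier-1
candidates exercise specificity. Peak/track simulation places CTCF/RAD21
peaks at active anchors (plus a configurable pre-bound fraction),
NIPBL∩RAD21 sites at a fixed fractional position inside gained loops,
H3K9me3 domains over gained-loop anchors at pre-formation stages, and
enhancer mark combinations with exact truth classes. ATAC inserts come
from truncated normals (TF: N(82, 15) on [30, 140]; Nuc: N(205, 20) on
[150, 280]) and raw coordinates are widened by the 9-bp Tn5 duplication
that the shift step removes.

What the generator does *not* emulate: TAD/insulation structure, trans
contacts, restriction-fragment bias, mappability artefacts, or loop
detection itself (candidate lists are inputs; planted truth stands in for
the caller). Passing the planted-truth tests therefore validates the
pipeline's arithmetic and statistical logic, not the upstream loop caller
or real-data noise structure.

## Numerical choices and test problem sizes

* KR tolerance 1e-6 (relative row-sum spread), max 3000 iterations, ICE
  fallback; overdispersion enters the generator only through depth jitter,
  so method-of-moments dispersion estimates near 0 are expected there and
  the NB path is exercised with explicit dispersions in tests.
* Pseudocounts: 0.5 per group mean in fold changes; 1e-6 floor in log2fc
  metaplots; input floor 1 read/bin in H3K9me3 ratios.
* Tie-breaks: earliest stage wins in assignments and merges; ties flagged.
* Test-suite problem sizes were chosen to keep the full suite within a few
  minutes on one CPU: null calibration uses a 10-Mb/10-kb chromosome at
  1×10⁶ contacts with 500 candidate loops over 50 seeds; recovery runs at
  the generator's default 20-Mb scale; APA calibration uses 150 loops per
  set on a pooled-replicate map (pooling replicates before VCsqrt + O/E is
  standard for aggregate maps and removes small-count median bias);
  permutation calibration uses 99 shuffles × 200 runs.

## Limitations

Cis-only (inter-chromosomal rows are dropped with a warning); one
chromosome per `contact_matrix` (multi-chromosome analyses loop over
objects); no .hic/.cool binary readers — matrices enter as bin-triplet
text; the exact NB test uses a single common dispersion rather than
empirical-Bayes tagwise shrinkage (pluggable by design); CTCF motif
orientation is consumed, never called.
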