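# loopshift

Stage-resolved chromatin-loop dynamics from binned contact matrices.

During stepwise differentiation (e.g. hESC → definitive endoderm →
primitive gut tube → pancreatic progenitor → islet organoid), CTCF/cohesin
loops form and dissolve at specific stages. `loopshift` is an R package
for quantifying that process from Hi-C/HiChIP-style contact maps together
with 1-D chromatin tracks. It is aimed at computational genomicists who
already have binned matrices, candidate loop lists (BEDPE) and peak/track
files, and want a tested, reproducible implementation of the downstream
statistics.

## What it computes

* **Normalization** — library subsampling to matched depth; Knight–Ruiz
  balancing (`v_i v_j O_ij` with equal row sums) and VCsqrt
  (`O_ij / sqrt(r_i r_j)`); distance normalization `(O − E)/(E + 1)` and
  the classic `O/E` ratio, with `E(d)` the mean contact at separation `d`;
  A/B compartment eigenvector of the Pearson correlation matrix at 25 kb.
* **Aggregate loop scores** — 21×21 pixel APA stacks at 10 kb with
  per-pixel median; APA score = center / mean of the 5×5 lower-right
  corner; meta score = center / median of the 2×2 top-right corner; corner
  categories 1–3 for condition differences; scaled metaplots mapping every
  loop span onto 10 equal bins.
* **Differential loops** — loop-union merge, 3×3 neighborhood
  quantification on subsampled counts, a two-sided exact negative-binomial
  test (conditional beta-binomial with common dispersion; identical to
  edgeR's exact test at equal library sizes), gates FDR < 0.1, p < 0.05,
  fold change ≥ 4; gained/lost direction and stage assignment by the
  max/min of the normalized frequency profile.
* **Anchor annotation** — ±5 kb peak occupancy (`both`/`one`/`none`),
  a 1000-shuffle chromosome-restricted permutation overlap test, the
  anchor-change taxonomy of new loops (extension / split / both-new /
  other), and ranking of loops by internal NIPBL∩RAD21 sites.
* **Tracks** — ATAC +4/−5 Tn5 shift and 50–115 / 180–247 bp partition,
  RPM bin matrices, enhancer / active-enhancer classification, 25-kb
  H3K9me3 positive and differential bins, expression changes of genes
  inside loop sets.
* **Synthetic truth** — a generator for multi-stage matrices
  (power-law decay, compartment checkerboard, planted loops with
  stage-specific multipliers, Poisson noise), peaks, tracks and ATAC
  fragments, so the entire pipeline is testable offline.

See `vignettes/loop-dynamics.Rmd` for the model details and design
decisions.

## Worked example

Simulate a five-stage time course with planted loops and run the full
pipeline (~20 s at this reduced scale):

```r
library(loopshift)
cfg <- sim_config(n_bins = 800, depth = 8e5, seed = 3)
res <- run_pipeline("demo_out", cfg, n_shuffles = 1000)
print(res$diff)
#> loop_diff: 140 loops over 5 stages (H9 -> DE -> PGT -> PP -> SCb)
#>   differential: 58, common: 82 (FDR < 0.1, p < 0.05, FC >= 4)
#>   common NB dispersion: 0
#>
#>          DE PGT PP SCb
#>   gained  8  10 10  10
#>   lost    5   5  5   5
```

140 union loops were tested; 58 are differential and are assigned to the
stage where their normalized contact frequency peaks (gained) or bottoms
(lost). Comparing against the planted truth:

```r
res$recovery
#>   sensitivity precision stage_accuracy direction_accuracy
#> 1   0.9666667         1              1                  1
res$apa
#>      set apa_score meta_score n_loops
#> 1 common  4.961759  5.3037165      39
#> 2   null  1.032741  0.9983336      40
```

58 of the 60 planted dynamic loops are recovered with no false positives,
every recovered loop is assigned to its true stage and direction, and the
APA score separates planted constitutive loops (~5× over local background)
from matched background pixels (~1.0). Anchor annotation closes the loop
with the simulated peaks:

```r
res$occupancy$fractions
#> both  one none
#>    1    0    0
res$shuffle$p_enrichment
#> [1] 0.000999001   # 1/(n+1) with n = 1000 shuffles
```

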