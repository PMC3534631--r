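# gflcnv — joint copy-number segmentation with a generalized fused lasso

`gflcnv` detects copy-number variants (CNVs) from SNP-array signals — Log R
Ratio (LRR) and B Allele Frequency (BAF) — by segmenting *several related
signal sequences jointly*: technical replicates or multiple platforms on one
subject, LRR together with mirrored BAF, tumor samples with normal-cell
contamination, or members of a pedigree who may share a variant. It is aimed
at statistical geneticists and bioinformaticians who want a fast,
transparent segmentation-plus-calling pipeline whose every tuning constant
is visible.

## The method

The piecewise-constant mean matrix β (M sequences × N probes) is estimated
by minimizing the generalized fused lasso objective

    ½ Σᵢⱼ δᵢⱼ (yᵢⱼ − βᵢⱼ)²  +  Σᵢ λ₁ᵢ Σⱼ |βᵢⱼ|
      +  Σᵢ λ₂ᵢ Σⱼ |βᵢⱼ − βᵢ,ⱼ₋₁|  +  Σⱼ ‖λ₃ ∗ (β₍ⱼ₎ − β₍ⱼ₋₁₎)‖₂ ,

a goodness-of-fit term over observed entries (mask δ allows sequences on
partially overlapping probe grids), a sparsity penalty toward the diploid
baseline, a per-sequence total-variation penalty, and a Euclidean group
penalty on each column of jumps that makes change points cheap to share
across sequences. The smoothed objective is minimized by an MM algorithm
whose inner step is one symmetric positive-definite tridiagonal solve per
sequence (Thomas algorithm, compiled) — O(MN) per iteration, with a
guaranteed monotone objective.

Around the solver the package provides: default penalty rules
λ₁ᵢ = c₁σ̂ᵢ, λ₂ᵢ = ρ(p)c₂σ̂ᵢ√(log N), λ₃ᵢ = (1−ρ(p))c₃σ̂ᵢ√(pM log N) driven
by a robust noise estimate σ̂ᵢ = MAD(Δyᵢ)/√2 and the expected sharing
proportion p; two-stage segmentation (lax fit, then the a=1/b=5/c=0.2
"ruler" threshold or a modified BIC, with jump collapsing, pruning and local
least-squares boundary refinement); a five-state likelihood-ratio caller on
BAF+LRR with the r₁ = 10 acceptance cutoff and the |ȳ| > r₂σ̂ mean-shift
guard; and synthetic-data generators (normal cohorts with inserted CNVs,
tumor–normal in-silico dilutions, pedigree-style shared variants) with
per-SNP TPR/FDR scoring.

## A worked example

```r
library(gflcnv)
set.seed(7)
sim <- generate_cohort(
  M = 3, N = 1200,
  specs = list(cnv_spec(301, 30, 1, carriers = 1),      # 30-probe deletion
               cnv_spec(801, 20, 3, carriers = 2:3)),   # shared 20-probe gain
  noise = noise_spec(lrr_sd = 0.25), seed = 7
)
signals <- dplyr::left_join(
  dplyr::rename(tidy(sim$lrr), lrr = "value", sample = "sequence"),
  dplyr::rename(tidy(sim$baf), baf = "value",
                sample = "sequence")[, c("sample", "position", "baf")],
  by = c("sample", "position")
)
cfg <- run_config(mode = "individual", signals = "both")
segments <- run_segment(signals, cfg)
calls <- run_call(segments, signals, cfg)
dplyr::filter(calls, accepted)
#>     sample chrom start end n_probes state   lr lrr_mean
#> 1 sample01     1   301 319       19     1 62.7   -0.622
#> 2 sample01     1   320 327        8     1 42.2   -0.870
#> 3 sample02     1   801 816       16     3 40.6    0.443
#> 4 sample03     1   801 807        7     3 17.8    0.535
#> 5 sample03     1   810 820       11     3 31.6    0.379
```

The deletion inserted at probes 301–330 of sample01 is recovered (split in
two adjacent accepted pieces, both called CN = 1 with log-likelihood ratios
62.7 and 42.2 against the diploid model), and the duplication shared by
samples 2 and 3 at probes 801–820 is called CN = 3 in both carriers; `lr` is
LR(ĉ) of the winning state and `lrr_mean` the segment's recomputed LRR mean.
Scoring against the generator's truth on a per-SNP basis:

```r
score_detection(sim$truth, calls)
#>   type        size  n_true n_called   tpr   fdr
#> 1 overall     all       70       61 0.871     0
#> 2 deletion    all       30       27 0.9       0
#> 3 duplication all       40       34 0.85      0
```

A thin command-line driver over the same functions is installed at
`inst/cli/gfl.R` (`simulate`, `segment`, `call`, `score` subcommands with
YAML/JSON configs).

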