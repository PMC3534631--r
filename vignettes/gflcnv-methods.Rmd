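---
title: "Joint copy-number segmentation with a generalized fused lasso"
author: "gflcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint copy-number segmentation with a generalized fused lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gflcnv)
```

## The model

SNP genotyping arrays deliver two signals per subject and probe: the Log R
Ratio (LRR), a normalized log2 total-intensity measure that is ≈ 0 at copy
number 2, and the B Allele Frequency (BAF), which clusters at
genotype-determined fractions. Copy-number variants (CNVs) shift the mean of
both. `gflcnv` reconstructs the piecewise-constant mean matrix
$\beta = (\beta_{ij})_{M \times N}$ of $M$ signal sequences observed at $N$
ordered genomic positions, $y_{ij} = \beta_{ij} + \varepsilon_{ij}$, by
minimizing

$$
f(\beta) = \tfrac12 \sum_{i,j} \delta_{ij}\,(y_{ij}-\beta_{ij})^2
 + \sum_i \lambda_{1,i} \sum_j |\beta_{ij}|
 + \sum_i \lambda_{2,i} \sum_{j\ge 2} |\beta_{ij}-\beta_{i,j-1}|
 + \sum_{j\ge 2} \bigl\lVert \lambda_3 * (\beta_{(j)}-\beta_{(j-1)}) \bigr\rVert_2 .
$$

The three penalties act in different directions: the lasso term pulls means to
the diploid baseline 0 (after normalization), the total-variation term makes
each sequence piecewise constant, and the Euclidean group term on each
*column* of jumps makes change points cheap to share across sequences — the
column relaxes for every member once one member jumps. Together the last two
behave like a sparse group lasso on jumps: some but not all sequences may
carry a variant. $\delta_{ij}$ masks unobserved entries, so sequences measured
at only partially overlapping positions (mirrored BAF lives on the
heterozygous subset of the LRR grid) are handled by stacking them on the
union grid; masked means are determined by the penalties from their
neighbours.

## The solver

The absolute values and the Euclidean norm are smoothed,
$|x| \to \sqrt{x^2+\varepsilon}$ and
$\lVert x\rVert \to \sqrt{\lVert x\rVert^2+\varepsilon}$, and the smoothed
objective is minimized by majorization–minimization: the concavity of the
square root gives a quadratic surrogate that touches the objective at the
current iterate and lies above it everywhere, so every step decreases the
objective. The surrogate separates over sequence rows into quadratics with
symmetric positive-definite *tridiagonal* Hessians, each solved exactly by
the Thomas algorithm (compiled, no pivoting) in $O(N)$, for $O(MN)$ per
iteration. This is what makes chromosome-scale joint fits cheap; chromosomes
are processed independently because a CNV cannot span two of them.

Numerical choices (all exposed in `penalty_config()`):

* `epsilon = 1e-8` on noise-normalized signals: the smoothing bias is of
  order $\sqrt{\varepsilon} = 10^{-4}$, far below any meaningful jump, while
  keeping the surrogate well conditioned.
* convergence when the relative objective decrease falls below `tol = 1e-6`
  *or* the iterate moves less than `beta_tol = 1e-6`; `max_iter = 500`.
  Non-convergence warns and returns the current iterate rather than failing.
* initialization at the observed data (masked entries 0), i.e. the
  unpenalized fit.
* coordinates with neither data nor penalty (possible only when all
  penalties are zero at a masked entry) are pinned to their current value so
  the tridiagonal systems stay non-singular.

The test suite checks the surrogate tangency/majorization contract to
$10^{-10}$, monotonicity of the objective trace on every instance, and
agreement of the final objective with an independent L-BFGS-B minimizer (with
analytic gradient) to $10^{-4}$ relative on random small instances.

## Default penalties

With $\hat\sigma_i$ a robust noise estimate per sequence (median absolute
deviation of first differences divided by $\sqrt2$; the handful of
differences bridging real change points barely move the MAD), the defaults
are

$$
\lambda_{1,i} = c_1\hat\sigma_i,\qquad
\lambda_{2,i} = \rho(p)\,c_2\hat\sigma_i\sqrt{\log N},\qquad
\lambda_{3,i} = [1-\rho(p)]\,c_3\hat\sigma_i\sqrt{p\,M\log N},
$$

with $c_1 = 0.1$, $c_2 = c_3 = 1$ and $\rho(p) = 1-p$, where $p$ is the
proportion of sequences expected to share a CNV: $p = 1$ for two signals of
one subject (jumps forced to coincide, $\lambda_2 = 0$), $p = 1/2$ for a
parent–offspring pair, $p = 0$ for unrelated sequences ($\lambda_3 = 0$).
$\rho$ is only constrained at its endpoints; the linear interpolant is the
simplest monotone choice. The $\sqrt{\log N}$ factor plays the usual
multiple-comparison role over the $N-1$ candidate jumps and the group term
grows with the expected carrier count $pM$ as in the original group-lasso
scaling. The sparsity term needs no $\log N$ factor: it acts as a soft
threshold on the already low-dimensional fused solution. Location-specific
down-weighting of the fusion penalties (e.g. in known copy-number
polymorphism regions) is available through `fusion_weights`.

## Two-stage segmentation

Reliable automatic selection of tight penalties is not available, so the
package follows a two-stage strategy: fit with deliberately lax penalties,
then hard-threshold the fitted jumps $\hat d_{ij} = \hat\beta_{ij} -
\hat\beta_{i,j-1}$ with a data-driven cutoff.

* **Ruler** (default): with $\hat D_i$ the largest absolute jump of sequence
  $i$, the ruler $\gamma_i = \max\{a\hat\sigma_i, \min(\hat D_i,
  b\hat\sigma_i)\}$ estimates the scale of a plausible real jump and jumps
  below $c\,\gamma_i$ are discarded; $a = 1$, $b = 5$, $c = 0.2$.
* **mBIC**: candidates ranked by decreasing $|\hat d|$ enter a nested
  normal-means model sequence scored by
  $\tfrac n2\log(RSS_0/RSS_k) - \tfrac12\sum_u \log(L_u/n) - \tfrac32 k\log
  n$; $\hat k = 0$ is allowed and is the typical answer on pure noise. The
  nested scan is capped at `k_max = 20` candidates: the lax stage emits many
  near-zero candidates (the smoothed solver never returns exact zeros), the
  criterion is maximized at small $k$, and the saturated tail of the path is
  both expensive and degenerate.

Three post-processing steps, each addressing a bias of the penalized fit,
complete the stage:

1. **Collapse** (`collapse_jumps`): one real boundary can be smeared over
   a short run of adjacent columns — especially by the group penalty when
   carriers prefer slightly different boundary probes — leaving each piece
   below the cutoff although the sum is a clear jump. Runs of same-sign
   candidates at consecutive indices are merged before thresholding;
   opposite signs (the two edges of a short CNV) never merge.
2. **Prune** (`prune_jumps`): after recomputing segment means from the
   observed data, a boundary (in particular one imposed by the union of
   LRR and mBAF change points) is kept only if some signal's mean
   difference still exceeds its cutoff.
3. **Refine** (`refine_jumps`): each surviving boundary is relocated to the
   local two-segment least-squares optimum within a 10-probe window,
   undoing the boundary smearing of the lax fit.

Segment means are recomputed as arithmetic means of the observed values: the
penalized levels are biased toward zero by roughly $\lambda_2/\text{segment
length}$, so reporting them would systematically understate CNV amplitudes.

## Copy-number calling

Each segment is assigned a state $c \in \{0,1,2,3,4\}$ by the log-likelihood
ratio $LR(c)$ of the segment's BAF and LRR values against the diploid model,
using canonical Illumina signal patterns: LRR normal around state means
$(-3.0, -0.66, 0, 0.40, 0.68)$ (gains compressed by saturation) with the
sample's own $\hat\sigma$; BAF a mixture over genotype clusters at $k/c$
with binomial($c$, $p_B$) weights, cluster SD 0.03 at the 0/1 boundary and
0.05 for heterozygote clusters, a 1% uniform outlier component, and a
uniform (uninformative) BAF at copy number 0. These explicit emission forms
are a reconstruction from the canonical cluster geometry; every constant is
exposed in `state_model()`. Array clipping is handled by censoring: values
exactly at 0/1 contribute cluster tail masses, and the uniform components
reserve 1% of their own mass at each boundary atom so no state has zero
likelihood at a clipped value.

A segment is reported as its argmax state only if $LR(\hat c) > r_1$
(default 10) *and* the absolute segment LRR mean exceeds $r_2\hat\sigma$
($r_2 = 1$ for gains, 1.5 for losses) — the second guard prevents long
diploid segments with small systematic LRR offsets from being called on
accumulated likelihood alone. Ties in the argmax prefer the state closer to
2, and the deletion on an exact-distance tie (deletions have the cleaner
signature); the rule is deterministic. Calling is always per sample, even
after joint segmentation.

## What the synthetic data emulates

`generate_cohort()` draws Hardy–Weinberg genotypes ($p_B = 0.5$,
independent across probes), Gaussian LRR noise around the state means, and
BAF from the genotype-cluster mixture with clipping and 1% outliers;
homozygote clusters use SD 0.01 (they are very tight on real arrays) and
heterozygote clusters 0.05. `generate_tumor_dilution()` mixes a tumor genome
with its matched normal at fraction $\alpha$: effective copy number
$n_{\rm eff} = 2\alpha + (1-\alpha)c$, LRR mean $\log_2(n_{\rm eff}/2)$
(floored at −5 where the mixture has no DNA — arrays saturate), BAF mean the
mixed B-allele share; copy-neutral LOH is expressed through allele counts
$(2,0)$. `generate_pedigree_cohort()` draws each variant's carriers
independently at a sharing proportion with at least one carrier forced.

What the generators deliberately do **not** emulate: real array noise is
autocorrelated (GC waves), genotypes are linked, BAF clusters drift by batch,
and the reference studies resample real X-chromosome intensities. Passing the
emulated studies therefore demonstrates that the estimator, tuning rules,
thresholding and caller work as designed at realistic signal-to-noise ratios
— not that the absolute accuracy numbers transfer to any particular platform.

## Problem sizes used in the checks

The packaged studies run at desk scale, chosen so the full suite completes in
minutes while keeping per-CNV probe counts, amplitudes and noise at the
reference operating point: cohorts of $M = 20$ samples and $N = 2600$ probes
with CNVs of 5–50 probes at $\sigma = 0.25$; dilution series at $N = 2000$
with a 500-probe hemizygous deletion; calling calibration on 50-probe
segments at $\sigma = 0.2$; mBIC characteristics at $n = 500$. The
joint-versus-individual power comparison is pooled over six replicate
cohorts because a single cohort contains only a dozen 10-probe carrier
events, fewer than the expected power difference resolves.

## Known limitations

* Penalty selection is rule-based; no data-adaptive tuning of $c_1..c_3$ or
  path following is provided, and a variable (per-region) sharing proportion
  is not estimated.
* The caller's five states do not include copy-neutral LOH as an output
  label, although the dilution generator can produce it (such regions are
  diploid in the truth used for scoring).
* mBAF uses a fixed heterozygote band (default 0.03–0.97) rather than
  genotype calls from a matched normal; with very tight homozygote clusters
  this occasionally lets a homozygote leak into the band as an mBAF outlier.
* The joint mode groups LRR sequences only; joint segmentation of LRR and
  mBAF across *multiple* samples simultaneously is not implemented.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
sim <- generate_cohort(
  M = 3, N = 1200,
  specs = list(cnv_spec(301, 30, 1, carriers = 1),
               cnv_spec(801, 20, 3, carriers = 2:3)),
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
score_detection(sim$truth, calls)
```
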