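#' Specify an inserted CNV for the synthetic generators
#'
#' @param start first probe index of the variant (1-based).
#' @param length number of probes spanned.
#' @param state integer copy-number state; `2` is only allowed together with
#'   `allele` counts describing copy-neutral LOH (e.g. `c(2, 0)`).
#' @param carriers indices of the sequences carrying the variant (ignored by
#'   the pedigree generator, which draws carriers at random).
#' @param allele optional tumor allele counts `c(nA, nB)` for heterozygous
#'   germline probes, used by [generate_tumor_dilution()]; must sum to `state`.
#' @return A `cnv_spec` list.
#' @export
cnv_spec <- function(start, length, state, carriers = 1L, allele = NULL) {
  stopifnot(start >= 1, length >= 1, state %in% 0:4)
  if (state == 2 && is.null(allele)) {
    stop("state 2 requires LOH `allele` counts (a CNV spec must deviate from diploid)",
         call. = FALSE)
  }
  if (!is.null(allele)) {
    stopifnot(length(allele) == 2, sum(allele) == state, all(allele >= 0))
  }
  if (length(carriers) == 0L) stop("`carriers` must be non-empty", call. = FALSE)
  structure(list(start = as.integer(start), length = as.integer(length),
                 state = as.integer(state), carriers = as.integer(carriers),
                 allele = allele),
            class = "cnv_spec")
}

#' Noise description for the synthetic generators
#'
#' @param lrr_sd per-sequence LRR noise SD (scalar or length M).
#' @param baf_sd_het,baf_sd_homo BAF cluster SDs away from / near the 0-1
#'   boundary; homozygote clusters on genotyping arrays are very tight, hence
#'   the 0.01 default.
#' @param outlier_frac fraction of BAF values replaced by uniform outliers.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(lrr_sd = 0.2, baf_sd_het = 0.05, baf_sd_homo = 0.01,
                       outlier_frac = 0.01) {
  stopifnot(all(lrr_sd > 0), baf_sd_het > 0, baf_sd_homo > 0,
            outlier_frac >= 0, outlier_frac < 1)
  structure(list(lrr_sd = lrr_sd, baf_sd_het = baf_sd_het,
                 baf_sd_homo = baf_sd_homo, outlier_frac = outlier_frac),
            class = "noise_spec")
}

# Sample a BAF value given a cluster center.
draw_baf <- function(center, noise) {
  n <- length(center)
  sd <- ifelse(center %in% c(0, 1), noise$baf_sd_homo, noise$baf_sd_het)
  x <- stats::rnorm(n, center, sd)
  out <- stats::runif(n) < noise$outlier_frac
  x[out] <- stats::runif(sum(out))
  pmin(pmax(x, 0), 1)
}

# B-allele copy count given germline genotype g (0/1/2 B alleles) and state.
draw_b_count <- function(g, state) {
  n <- length(g)
  b <- numeric(n)
  hom0 <- g == 0L; hom2 <- g == 2L; het <- g == 1L
  b[hom0] <- 0
  b[hom2] <- state
  nh <- sum(het)
  if (nh > 0) {
    b[het] <- switch(as.character(state),
      "0" = 0,
      "1" = stats::rbinom(nh, 1, 0.5),           # surviving allele A or B
      "2" = 1,
      "3" = 1 + stats::rbinom(nh, 1, 0.5),       # one extra copy, either allele
      "4" = 1 + stats::rbinom(nh, 2, 0.5))       # two extra copies, independent
  }
  b
}

truth_table <- function(cn, specs, labels, positions, chrom) {
  segs <- purrr::map_dfr(specs, function(sp) {
    tibble::tibble(sequence = labels[sp$carriers], chrom = chrom,
                   start = sp$start, end = sp$start + sp$length - 1L,
                   start_bp = positions[sp$start],
                   end_bp = positions[sp$start + sp$length - 1L],
                   n_probes = sp$length, cn = sp$state,
                   loh = !is.null(sp$allele) && sp$state == 2L)
  })
  structure(list(cn = cn, segments = segs, labels = labels,
                 positions = positions, chrom = chrom),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d x %d, %d variant segment record%s\n",
              nrow(x$cn), ncol(x$cn), nrow(x$segments),
              if (nrow(x$segments) == 1) "" else "s"))
  invisible(x)
}

check_specs <- function(specs, M, N) {
  occupied <- matrix(FALSE, M, N)
  for (sp in specs) {
    if (!inherits(sp, "cnv_spec")) stop("each spec must be a cnv_spec", call. = FALSE)
    end <- sp$start + sp$length - 1L
    if (end > N) stop("CNV spec exceeds the probe range 1..N", call. = FALSE)
    if (any(sp$carriers < 1 | sp$carriers > M)) {
      stop("carriers must index sequences 1..M", call. = FALSE)
    }
    if (any(occupied[sp$carriers, sp$start:end])) {
      stop("overlapping CNV specs for one carrier", call. = FALSE)
    }
    occupied[sp$carriers, sp$start:end] <- TRUE
  }
  invisible(TRUE)
}

#' Generate a cohort of normal samples with inserted CNVs
#'
#' Emulates SNP-array experiments on M diploid samples over N probes:
#' germline genotypes are drawn Hardy-Weinberg at B-allele frequency `p_b`
#' independently across probes, LRR is Gaussian around the state mean of
#' `model`, and BAF is drawn from the state's genotype-cluster mixture with
#' clipping to \[0, 1\] and a small uniform outlier fraction. The listed CNVs
#' overwrite the diploid truth for their carriers.
#'
#' @param M,N number of samples and probes.
#' @param specs list of [cnv_spec()]s, non-overlapping per carrier.
#' @param noise a [noise_spec()].
#' @param model a [state_model()] supplying LRR state means and `p_b`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param chrom chromosome label.
#' @param positions probe positions (default a regular 1 kb grid).
#' @return List with `lrr` and `baf` ([signal_matrix()]s, fully observed) and
#'   `truth` (a `truth_table`: per-probe CN matrix plus variant segments).
#' @export
#' @examples
#' sim <- generate_cohort(2, 200, list(cnv_spec(91, 20, 1, carriers = 1)), seed = 7)
#' table(sim$truth$cn)
generate_cohort <- function(M, N, specs = list(), noise = noise_spec(),
                            model = state_model(), seed = NULL, chrom = "1",
                            positions = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq(1000, by = 1000, length.out = N)
  check_specs(specs, M, N)
  labels <- sprintf("sample%02d", seq_len(M))
  cn <- matrix(2L, M, N)
  for (sp in specs) {
    cn[sp$carriers, sp$start:(sp$start + sp$length - 1L)] <- sp$state
  }
  lrr_sd <- rep_len(noise$lrr_sd, M)
  g <- matrix(stats::rbinom(M * N, 2, model$p_b), M, N)
  lrr <- matrix(stats::rnorm(M * N, model$lrr_mean[cn + 1L], rep(lrr_sd, N)), M, N)
  b <- matrix(0, M, N)
  for (s in unique(as.vector(cn))) {
    idx <- cn == s
    b[idx] <- draw_b_count(g[idx], s)
  }
  center <- ifelse(cn == 0L, NA_real_, b / pmax(cn, 1L))
  baf <- matrix(draw_baf(ifelse(is.na(center), 0.5, center), noise), M, N)
  if (any(cn == 0L)) baf[cn == 0L] <- stats::runif(sum(cn == 0L))
  list(
    lrr = signal_matrix(lrr, chrom = chrom, positions = positions, labels = labels),
    baf = signal_matrix(baf, chrom = chrom, positions = positions, labels = labels),
    truth = truth_table(cn, specs, labels, positions, chrom)
  )
}

#' Generate an in-silico diluted tumor sample
#'
#' Simulates a tumor genome carrying the listed aberrations (one-copy losses
#' and gains, homozygous deletions, copy-neutral LOH via `allele` counts) and
#' contaminates it with the matched normal at fraction `alpha`: the effective
#' copy number at a probe is `n_eff = 2 alpha + (1 - alpha) c_tumor`, the LRR
#' mean is `log2(n_eff / 2)` (floored at `lrr_floor` where the mixture has no
#' DNA), and the BAF mean is the mixed B-allele share
#' `(alpha g + (1 - alpha) nB) / n_eff` for germline genotype `g`. Noise is
#' added as in [generate_cohort()].
#'
#' @param specs list of [cnv_spec()]s (carriers ignored; one tumor sequence).
#' @param alpha normal-cell fraction in \[0, 1\].
#' @param noise a [noise_spec()].
#' @param N number of probes.
#' @param model a [state_model()] (supplies `p_b`).
#' @param seed integer seed.
#' @param chrom,positions as in [generate_cohort()].
#' @param lrr_floor LRR mean for zero effective copies (array saturation).
#' @return List with `lrr`, `baf` (single-sequence [signal_matrix()]s) and
#'   `truth` (tumor copy numbers; contamination does not change the truth).
#' @export
generate_tumor_dilution <- function(specs, alpha, noise = noise_spec(),
                                    N = 2000, model = state_model(),
                                    seed = NULL, chrom = "1",
                                    positions = NULL, lrr_floor = -5) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq(1000, by = 1000, length.out = N)
  specs <- lapply(specs, function(sp) { sp$carriers <- 1L; sp })
  check_specs(specs, 1L, N)
  cn <- rep(2L, N)
  loh <- rep(FALSE, N)
  allele_of <- vector("list", N)
  for (sp in specs) {
    idx <- sp$start:(sp$start + sp$length - 1L)
    cn[idx] <- sp$state
    if (!is.null(sp$allele)) {
      loh[idx] <- sp$state == 2L
      allele_of[idx] <- list(sp$allele)
    }
  }
  g <- stats::rbinom(N, 2, model$p_b)
  nB <- numeric(N)
  for (j in seq_len(N)) {
    al <- allele_of[[j]]
    if (!is.null(al)) {
      nB[j] <- switch(as.character(g[j]),
                      "0" = 0, "2" = cn[j],
                      # het: which germline haplotype got which fate is unphased
                      "1" = sample(c(al[2], cn[j] - al[2]), 1))
    } else {
      nB[j] <- draw_b_count(g[j], cn[j])
    }
  }
  n_eff <- 2 * alpha + (1 - alpha) * cn
  b_eff <- alpha * g + (1 - alpha) * nB
  lrr_mean <- ifelse(n_eff > 0, log2(n_eff / 2), lrr_floor)
  lrr_mean <- pmax(lrr_mean, lrr_floor)
  lrr <- stats::rnorm(N, lrr_mean, rep_len(noise$lrr_sd, 1))
  baf_center <- ifelse(n_eff > 0, b_eff / n_eff, NA_real_)
  baf <- draw_baf(ifelse(is.na(baf_center), 0.5, baf_center), noise)
  if (any(n_eff == 0)) baf[n_eff == 0] <- stats::runif(sum(n_eff == 0))
  cn_mat <- matrix(cn, 1L, N)
  tt <- truth_table(cn_mat, specs, "tumor", positions, chrom)
  list(
    lrr = signal_matrix(matrix(lrr, 1L), chrom = chrom, positions = positions,
                        labels = "tumor"),
    baf = signal_matrix(matrix(baf, 1L), chrom = chrom, positions = positions,
                        labels = "tumor"),
    truth = tt,
    alpha = alpha
  )
}

#' Generate a pedigree-style cohort with partially shared CNVs
#'
#' As [generate_cohort()], but each CNV's carrier set is drawn at random:
#' every sequence carries the variant independently with probability
#' `p_share`, with at least one carrier forced (a variant absent from all
#' sequences would be undetectable by construction).
#'
#' @inheritParams generate_cohort
#' @param p_share expected carrier proportion, `0 < p_share <= 1`.
#' @return As [generate_cohort()].
#' @export
generate_pedigree_cohort <- function(M, N, p_share, specs, noise = noise_spec(),
                                     model = state_model(), seed = NULL,
                                     chrom = "1", positions = NULL) {
  if (!is.finite(p_share) || p_share <= 0 || p_share > 1) {
    stop("`p_share` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  specs <- lapply(specs, function(sp) {
    carriers <- which(stats::runif(M) < p_share)
    if (length(carriers) == 0L) carriers <- sample.int(M, 1L)
    sp$carriers <- carriers
    sp
  })
  generate_cohort(M, N, specs, noise, model, seed = NULL, chrom = chrom,
                  positions = positions)
}

#' Per-SNP detection accuracy against a simulation truth
#'
#' Compares accepted copy-number calls with the generating truth on a per-SNP
#' basis. A probe counts as a true positive when its true copy number differs
#' from 2 and it is covered by an accepted non-diploid call; the true positive
#' rate is TP / (true variant probes) and the false discovery rate is the
#' fraction of called-variant probes whose truth is diploid. Rates are broken
#' out by variant type (deletion / duplication) and, for TPR, by CNV length
#' class. Copy-neutral LOH truth probes have true CN 2 and are excluded from
#' both the variant truth and the FDR denominator's truth-normal set.
#'
#' @param truth a `truth_table` from a generator.
#' @param calls a calls tibble (from [call_segments()]): columns `sequence`,
#'   `start`, `end`, `state`, `accepted`.
#' @return Tibble with rows per (type, size class) plus type and overall
#'   summaries: `type`, `size`, `n_true`, `n_called`, `tpr`, `fdr`,
#'   `no_calls` (TRUE when `fdr` is reported as 0 for lack of any call).
#' @export
score_detection <- function(truth, calls) {
  M <- nrow(truth$cn); N <- ncol(truth$cn)
  called <- matrix(2L, M, N)
  if (!"sequence" %in% names(calls) && "sample" %in% names(calls)) {
    calls$sequence <- calls$sample
  }
  acc <- calls[calls$accepted & calls$state != 2L, , drop = FALSE]
  for (r in seq_len(nrow(acc))) {
    i <- match(acc$sequence[r], truth$labels)
    if (is.na(i)) stop("call for unknown sequence '", acc$sequence[r], "'", call. = FALSE)
    called[i, acc$start[r]:acc$end[r]] <- acc$state[r]
  }
  tv <- truth$cn != 2L
  cv <- called != 2L
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  fdr_of <- function(sel_called) {
    den <- sum(sel_called)
    list(fdr = if (den > 0) sum(sel_called & !tv) / den else 0, none = den == 0)
  }
  row_for <- function(type, size, sel_true, sel_called) {
    f <- fdr_of(sel_called)
    tibble::tibble(type = type, size = size,
                   n_true = sum(sel_true), n_called = sum(sel_called),
                   tpr = rate(sum(cv & sel_true), sum(sel_true)),
                   fdr = f$fdr, no_calls = f$none)
  }
  out <- row_for("overall", "all", tv, cv)
  sel_del_t <- truth$cn < 2L
  sel_dup_t <- truth$cn > 2L
  out <- dplyr::bind_rows(out,
    row_for("deletion", "all", sel_del_t, called < 2L),
    row_for("duplication", "all", sel_dup_t, called > 2L))
  segs <- truth$segments[!truth$segments$loh, , drop = FALSE]
  if (nrow(segs) > 0) {
    segs$type <- ifelse(segs$cn < 2L, "deletion", "duplication")
    by_class <- dplyr::distinct(segs, .data$type, .data$n_probes)
    out <- dplyr::bind_rows(out, purrr::map_dfr(seq_len(nrow(by_class)), function(k) {
      sub <- segs[segs$type == by_class$type[k] & segs$n_probes == by_class$n_probes[k], ]
      sel <- matrix(FALSE, M, N)
      for (r in seq_len(nrow(sub))) {
        i <- match(sub$sequence[r], truth$labels)
        sel[i, sub$start[r]:sub$end[r]] <- TRUE
      }
      sel <- sel & tv
      row_for(by_class$type[k], as.character(by_class$n_probes[k]),
              sel, matrix(FALSE, M, N))[, c("type", "size", "n_true", "tpr")]
    }))
  }
  out
}
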