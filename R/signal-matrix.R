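#' Multi-sequence signal matrix on a shared probe grid
#'
#' A `signal_matrix` holds M signal sequences (rows) measured on a common,
#' strictly increasing grid of N genomic probe positions (columns), together
#' with an observation mask. Entry `values[i, j]` is the observed value of
#' sequence `i` at probe `j` (Log R Ratio in log2-ratio units, or mirrored BAF
#' in allele-fraction units); `mask[i, j] == 1` marks positions where sequence
#' `i` was actually measured. Masked-out entries carry no information: they are
#' stored as `NA` and excluded from every data term, and the solver fills the
#' corresponding means from the fusion penalties alone.
#'
#' @param values numeric M x N matrix; `NA`/non-finite entries are treated as
#'   missing and masked out.
#' @param chrom single chromosome label shared by all probes.
#' @param positions strictly increasing genomic coordinates (1-based bp),
#'   length N.
#' @param mask optional M x N 0/1 matrix; defaults to `is.finite(values)`.
#'   Where given, it must be 1 only at finite values and is authoritative:
#'   values at `mask == 0` are replaced by `NA`.
#' @param probe_names optional probe identifiers, length N.
#' @param labels optional sequence identifiers, length M.
#'
#' @return An object of class `signal_matrix`: a list with elements `values`,
#'   `mask`, `chrom`, `positions`, `probe_names`, `labels`.
#' @export
#' @examples
#' y <- rbind(rnorm(10), rnorm(10))
#' sm <- signal_matrix(y, chrom = "1", positions = seq(1000, by = 500, length.out = 10))
#' sm
signal_matrix <- function(values, chrom, positions, mask = NULL,
                          probe_names = NULL, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  M <- nrow(values)
  N <- ncol(values)
  if (length(chrom) != 1L) stop("`chrom` must be a single chromosome label", call. = FALSE)
  positions <- as.numeric(positions)
  if (length(positions) != N) {
    stop("`positions` must have one entry per column of `values`", call. = FALSE)
  }
  if (N > 1L && any(diff(positions) <= 0)) {
    stop("probe positions must be strictly increasing (no duplicates)", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- is.finite(values) * 1
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(values))) stop("`mask` dimensions must match `values`", call. = FALSE)
    if (!all(mask %in% c(0, 1))) stop("`mask` must be a 0/1 indicator matrix", call. = FALSE)
    if (any(mask == 1 & !is.finite(values))) {
      stop("`mask` marks observed entries that are not finite", call. = FALSE)
    }
    storage.mode(mask) <- "double"
  }
  values[mask == 0] <- NA_real_
  if (any(colSums(mask) == 0)) {
    stop("every probe must be observed in at least one sequence (grid is the union of observed positions)",
         call. = FALSE)
  }
  if (is.null(probe_names)) probe_names <- paste0("p", seq_len(N))
  if (length(probe_names) != N) stop("`probe_names` must have length N", call. = FALSE)
  if (is.null(labels)) labels <- paste0("seq", seq_len(M))
  if (length(labels) != M) stop("`labels` must have length M", call. = FALSE)
  structure(
    list(values = values, mask = mask, chrom = as.character(chrom),
         positions = positions, probe_names = as.character(probe_names),
         labels = as.character(labels)),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  M <- nrow(x$values); N <- ncol(x$values)
  obs <- sum(x$mask)
  cat(sprintf("<signal_matrix> %d sequence%s x %d probes on chr%s (%.1f%% observed)\n",
              M, if (M == 1) "" else "s", N, x$chrom, 100 * obs / (M * N)))
  cat("  sequences:", paste(utils::head(x$labels, 6), collapse = ", "),
      if (M > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Convert a signal matrix to a long tibble
#'
#' @param x a [signal_matrix()].
#' @param ... unused.
#' @return A tibble with columns `sequence`, `chrom`, `position`, `probe`,
#'   `value`, `observed` (one row per sequence x probe).
#' @export
tidy.signal_matrix <- function(x, ...) {
  M <- nrow(x$values); N <- ncol(x$values)
  tibble::tibble(
    sequence = rep(x$labels, times = N),
    chrom = x$chrom,
    position = rep(x$positions, each = M),
    probe = rep(x$probe_names, each = M),
    value = as.vector(x$values),
    observed = as.vector(x$mask) == 1
  )
}

#' Stack sequences measured at partially overlapping positions
#'
#' Builds a [signal_matrix()] on the sorted union S of all positions at which
#' any track has a measurement. The mask is 1 exactly where a track has its own
#' measurement; placeholder values elsewhere are `NA` and excluded from all
#' data terms downstream.
#'
#' @param tracks a list of tracks, each a list (or data frame) with elements
#'   `chrom` (scalar), `positions` and `values` (equal-length vectors).
#'   Data-frame tracks may use columns `chrom`, `position`, `value`.
#' @param labels optional sequence labels (defaults to track names).
#' @return A [signal_matrix()] on the union grid.
#' @export
#' @examples
#' a <- list(chrom = "7", positions = c(10, 20, 30), values = c(1, 1, 5))
#' b <- list(chrom = "7", positions = c(15, 20, 40, 50), values = c(0, 0, 2, 2))
#' stack_sequences(list(lrr = a, mbaf = b))
stack_sequences <- function(tracks, labels = NULL) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop("`tracks` must be a non-empty list", call. = FALSE)
  }
  tracks <- lapply(tracks, function(tr) {
    if (is.data.frame(tr)) {
      list(chrom = tr$chrom[1], positions = tr$position, values = tr$value)
    } else tr
  })
  chroms <- vapply(tracks, function(tr) as.character(tr$chrom[1]), character(1))
  if (length(unique(chroms)) != 1L) {
    stop("all tracks must be on the same chromosome; got: ",
         paste(unique(chroms), collapse = ", "), call. = FALSE)
  }
  for (k in seq_along(tracks)) {
    pos <- tracks[[k]]$positions
    if (anyDuplicated(pos)) stop("duplicate position within track ", k, call. = FALSE)
    if (length(pos) != length(tracks[[k]]$values)) {
      stop("positions/values length mismatch in track ", k, call. = FALSE)
    }
  }
  S <- sort(unique(unlist(lapply(tracks, `[[`, "positions"))))
  M <- length(tracks); N <- length(S)
  values <- matrix(NA_real_, M, N)
  mask <- matrix(0, M, N)
  for (i in seq_len(M)) {
    ord <- order(tracks[[i]]$positions)
    j <- match(tracks[[i]]$positions[ord], S)
    values[i, j] <- tracks[[i]]$values[ord]
    mask[i, j] <- ifelse(is.finite(values[i, j]), 1, 0)
  }
  values[mask == 0] <- NA_real_
  if (is.null(labels)) {
    labels <- names(tracks)
    if (is.null(labels) || any(labels == "")) labels <- paste0("seq", seq_len(M))
  }
  signal_matrix(values, chrom = chroms[1], positions = S, mask = mask, labels = labels)
}

#' Mirrored B Allele Frequency transform
#'
#' Folds BAF about 1/2, `mBAF = max(BAF, 1 - BAF)`, and masks out apparent
#' homozygotes (BAF outside the heterozygote band and its mirror image) and
#' missing entries. The two alleles are exchangeable, so the fold loses no
#' information, while homozygous SNPs carry almost none and are dropped; the
#' result lives on a coarser grid than the input BAF but has a mean that
#' shifts in the presence of a CNV.
#'
#' @param baf numeric vector of B allele frequencies in \[0, 1\] (`NA` allowed).
#' @param het_band length-2 numeric `(lo, hi)` with `0 < lo < hi < 1`: BAF
#'   values in `(lo, hi)` or `(1 - hi, 1 - lo)` are treated as heterozygous
#'   (in practice the band is symmetric, so the union is just `(lo, hi)`).
#'   The default excludes BAF within 0.03 of 0 or 1 as homozygous.
#' @return A list with `mbaf` (vector, `NA` where masked) and `mask`
#'   (0/1 vector, 1 = retained heterozygote).
#' @export
#' @examples
#' compute_mbaf(c(0.5, 0.3, 0.995, NA))
compute_mbaf <- function(baf, het_band = c(0.03, 0.97)) {
  if (length(het_band) != 2L || !all(is.finite(het_band)) || het_band[1] >= het_band[2]) {
    stop("`het_band` must be finite (lo, hi) with lo < hi", call. = FALSE)
  }
  bad <- is.finite(baf) & (baf < 0 | baf > 1)
  if (any(bad)) stop("BAF values must lie in [0, 1]", call. = FALSE)
  lo <- het_band[1]; hi <- het_band[2]
  het <- is.finite(baf) &
    ((baf > lo & baf < hi) | (baf > 1 - hi & baf < 1 - lo))
  mbaf <- ifelse(het, pmax(baf, 1 - baf), NA_real_)
  list(mbaf = mbaf, mask = as.numeric(het))
}

#' Robust per-sequence noise-level estimate
#'
#' Estimates the noise standard deviation of a piecewise-constant signal from
#' first-order differences of consecutive observed values: within a constant
#' segment `Var(y[j+1] - y[j]) = 2 * sigma^2`, and only the few differences
#' bridging real change points deviate, so `sigma_hat = SD(diff(y)) / sqrt(2)`
#' with a robust dispersion estimate. Differences are taken between consecutive
#' observed entries regardless of the genomic gap (the estimator is index-based).
#'
#' @param y numeric vector, `NA` = missing; at least 3 observed values.
#' @param method `"mad"` (default; normal-consistent median absolute deviation,
#'   robust to the change points being sought) or `"sd"`.
#' @return Non-negative scalar estimate of the per-probe noise SD.
#' @export
#' @examples
#' estimate_sigma(rnorm(1000, sd = 0.25))
estimate_sigma <- function(y, method = c("mad", "sd")) {
  method <- match.arg(method)
  obs <- y[is.finite(y)]
  if (length(obs) < 3L) {
    stop("need at least 3 observed values to estimate sigma", call. = FALSE)
  }
  d <- diff(obs)
  disp <- switch(method, mad = stats::mad(d), sd = stats::sd(d))
  disp / sqrt(2)
}
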