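#' Extract candidate jumps from a fitted mean matrix
#'
#' Finite-differences each row of the fitted means and keeps positions whose
#' absolute jump exceeds a numerical floor. The eps-smoothed solver returns
#' near-zero rather than exactly zero differences, so the floor (default
#' `1e-6 * sigma_i`, far below any scientifically meaningful jump) separates
#' numerical dust from candidates.
#'
#' @param fit a `gfl_fit` from [fit_gfl()], or an M x N matrix of means.
#' @param floor numerical floor(s), scalar or per sequence; default
#'   `1e-6 * sigma`, or `1e-6 * max(abs(beta))` when `sigma` is absent.
#' @param sigma optional per-sequence noise SDs used for the default floor.
#' @param labels sequence labels when `fit` is a bare matrix.
#' @return A jump-set tibble with columns `sequence`, `j` (probe index in
#'   2..N: the jump sits between probes `j - 1` and `j`), `size`
#'   (`beta[i, j] - beta[i, j - 1]`), ordered by sequence then index.
#' @export
extract_jumps <- function(fit, floor = NULL, sigma = NULL, labels = NULL) {
  if (inherits(fit, "gfl_fit")) {
    beta <- fit$beta
    labels <- fit$data$labels
  } else {
    beta <- as.matrix(fit)
    if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(beta)))
  }
  if (!all(is.finite(beta))) stop("`beta` must be finite", call. = FALSE)
  M <- nrow(beta); N <- ncol(beta)
  if (is.null(floor)) {
    floor <- if (!is.null(sigma)) 1e-6 * sigma else 1e-6 * max(abs(beta), 1e-12)
  }
  if (length(floor) == 1L) floor <- rep(floor, M)
  d <- beta[, -1, drop = FALSE] - beta[, -N, drop = FALSE]
  keep <- abs(d) > floor
  out <- purrr::map_dfr(seq_len(M), function(i) {
    js <- which(keep[i, ])
    tibble::tibble(sequence = labels[i], j = js + 1L, size = d[i, js])
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(sequence = character(), j = integer(), size = numeric())
  }
  out
}

#' Collapse smeared jumps before thresholding
#'
#' The penalized fit — in particular the group penalty, when different
#' sequences prefer slightly different boundary probes — can smear one real
#' jump across a short run of consecutive columns, leaving every piece below
#' the hard threshold although their sum is a clear jump. This step merges
#' runs of same-sign candidate jumps at consecutive probe indices into a
#' single candidate carrying the summed size, located at the largest piece.
#' Opposite-sign neighbours (e.g. the two edges of a short CNV) are never
#' merged.
#'
#' @param jumps candidate jump-set tibble from [extract_jumps()].
#' @param gap maximum index spacing treated as consecutive (default 1).
#' @return Collapsed jump-set tibble.
#' @export
collapse_jumps <- function(jumps, gap = 1L) {
  if (nrow(jumps) == 0L) return(jumps)
  purrr::map_dfr(unique(jumps$sequence), function(lab) {
    own <- jumps[jumps$sequence == lab, , drop = FALSE]
    own <- own[order(own$j), , drop = FALSE]
    new_run <- c(TRUE, diff(own$j) > gap | diff(sign(own$size)) != 0)
    run <- cumsum(new_run)
    purrr::map_dfr(split(own, run), function(cl) {
      tibble::tibble(sequence = lab,
                     j = cl$j[which.max(abs(cl$size))],
                     size = sum(cl$size))
    })
  })
}

#' Threshold jumps with the data-adaptive "ruler" heuristic
#'
#' Second stage of the two-stage strategy: after a lax penalized fit, small
#' jumps are removed with a cutoff expressed as a fraction of a per-sequence
#' ruler. With `D_i` the largest absolute jump of sequence `i`, the ruler is
#' `gamma_i = max(a * sigma_i, min(D_i, b * sigma_i))` — the scale of a
#' plausible real jump, clamped between `a` and `b` noise SDs — and jumps with
#' `|size| <= c * gamma_i` are dropped. Defaults `a = 1`, `b = 5`, `c = 0.2`.
#' The retained set is invariant to rescaling the signal, fit and `sigma`
#' together.
#'
#' @param jumps jump-set tibble from [extract_jumps()].
#' @param sigma per-sequence noise SDs: a named vector (names = sequence
#'   labels), or a scalar, or in order of first appearance.
#' @param a,b,c ruler constants, `0 < a < b`, `0 < c < 1`.
#' @return The retained subset of `jumps` with an extra `cutoff` column.
#' @export
ruler_threshold <- function(jumps, sigma, a = 1, b = 5, c = 0.2) {
  if (!(a > 0 && b > a)) stop("need 0 < a < b", call. = FALSE)
  if (!(c > 0 && c < 1)) stop("need 0 < c < 1", call. = FALSE)
  seqs <- unique(jumps$sequence)
  if (is.null(names(sigma))) {
    sigma <- if (length(sigma) == 1L) setNames(rep(sigma, length(seqs)), seqs)
             else setNames(sigma, seqs)
  }
  out <- dplyr::group_by(jumps, .data$sequence)
  out <- dplyr::group_modify(out, function(df, key) {
    s <- sigma[[as.character(key$sequence)]]
    if (nrow(df) > 0 && (!is.finite(s) || s <= 0)) {
      stop("degenerate noise scale (sigma <= 0) for sequence ", key$sequence, call. = FALSE)
    }
    D <- max(abs(df$size))
    gamma <- max(a * s, min(D, b * s))
    df$cutoff <- c * gamma
    df[abs(df$size) > df$cutoff, , drop = FALSE]
  })
  dplyr::ungroup(out)
}

#' Select change points with a modified BIC
#'
#' Alternative second stage: candidate jumps are ranked by decreasing
#' absolute size (ties broken by earlier index) and added one at a time to a
#' nested sequence of piecewise-constant normal-means models for the observed
#' values; the retained number of change points maximizes
#' \deqn{mBIC(k) = \frac{n}{2}\log\frac{RSS_0}{RSS_k}
#'   - \frac12 \sum_{u=1}^{k+1} \log\frac{L_u}{n} - \kappa\, k \log n,}
#' with `L_u` the observed segment lengths and `n` the observed count.
#' `k = 0` (no change point) is allowed and is the typical answer on pure
#' noise. Masked probes count toward neither `L_u` nor the segment means.
#'
#' @param y numeric vector for one sequence on the probe grid (`NA` = masked).
#' @param candidates data frame with columns `j` (probe index 2..N) and
#'   `size`, or a bare integer vector of candidate indices.
#' @param kappa change-point penalty constant, default `3/2`.
#' @param k_max maximum number of change points scanned (the lax first stage
#'   can emit hundreds of near-zero candidates; the criterion is maximized at
#'   small `k`, so the nested scan is capped for cost).
#' @return Integer vector of retained change-point indices (sorted), possibly
#'   empty.
#' @export
mbic_threshold <- function(y, candidates, kappa = 1.5, k_max = 20L) {
  if (is.data.frame(candidates)) {
    ord <- order(-abs(candidates$size), candidates$j)
    cand <- as.integer(candidates$j[ord])
  } else {
    cand <- as.integer(candidates)
  }
  cand <- cand[!duplicated(cand)]
  cand <- head(cand, k_max)
  N <- length(y)
  obs <- is.finite(y)
  n <- sum(obs)
  if (n < 2L || length(cand) == 0L) return(integer(0))

  seg_rss <- function(bounds) {
    # bounds: sorted change-point indices; segments [1,b1-1],[b1,b2-1],...
    starts <- c(1L, bounds)
    ends <- c(bounds - 1L, N)
    rss <- 0; lens <- numeric(length(starts)); ok <- TRUE
    for (u in seq_along(starts)) {
      v <- y[starts[u]:ends[u]]
      v <- v[is.finite(v)]
      lens[u] <- length(v)
      if (length(v) == 0L) ok <- FALSE
      else rss <- rss + sum((v - mean(v))^2)
    }
    list(rss = rss, lens = lens, ok = ok)
  }

  base <- seg_rss(integer(0))
  rss0 <- base$rss
  scores <- numeric(length(cand) + 1L)
  scores[1] <- 0   # k = 0 reference
  for (k in seq_along(cand)) {
    cur <- seg_rss(sort(cand[seq_len(k)]))
    if (!cur$ok || cur$rss <= 0) {
      scores[k + 1L] <- if (!cur$ok) -Inf else Inf
    } else {
      scores[k + 1L] <- (n / 2) * log(rss0 / cur$rss) -
        0.5 * sum(log(cur$lens / n)) - kappa * k * log(n)
    }
  }
  khat <- which.max(scores) - 1L
  sort(cand[seq_len(khat)])
}

#' Materialize segments from retained jumps
#'
#' Cuts each sequence at its retained change points and recomputes every
#' segment mean as the arithmetic mean of the observed values it spans (the
#' penalized fit is biased toward zero by roughly `lambda2 / segment length`,
#' so means are re-estimated from the data). Segments containing no observed
#' probe inherit the fitted level and are flagged.
#'
#' @param jumps jump-set tibble (columns `sequence`, `j`); sequences of `data`
#'   with no rows in `jumps` get a single segment.
#' @param data the [signal_matrix()] that was segmented.
#' @param beta optional fitted mean matrix, used for zero-observation segments.
#' @return A segment tibble: `sequence`, `chrom`, `start`, `end` (1-based
#'   inclusive probe indices), `start_bp`, `end_bp` (positions of the boundary
#'   probes), `n_probes`, `n_obs`, `mean`, `fitted_only`. Segments partition
#'   `1..N` for every sequence.
#' @export
jumps_to_segments <- function(jumps, data, beta = NULL) {
  stopifnot(inherits(data, "signal_matrix"))
  N <- ncol(data$values)
  purrr::map_dfr(seq_along(data$labels), function(i) {
    lab <- data$labels[i]
    js <- sort(unique(jumps$j[jumps$sequence == lab]))
    js <- js[js >= 2 & js <= N]
    starts <- c(1L, as.integer(js))
    ends <- c(as.integer(js) - 1L, N)
    y <- data$values[i, ]
    purrr::map_dfr(seq_along(starts), function(u) {
      idx <- starts[u]:ends[u]
      v <- y[idx][is.finite(y[idx])]
      fitted_only <- length(v) == 0L
      m <- if (fitted_only) {
        if (is.null(beta)) NA_real_ else mean(beta[i, idx])
      } else mean(v)
      tibble::tibble(
        sequence = lab, chrom = data$chrom,
        start = starts[u], end = ends[u],
        start_bp = data$positions[starts[u]], end_bp = data$positions[ends[u]],
        n_probes = length(idx), n_obs = length(v),
        mean = m, fitted_only = fitted_only
      )
    })
  })
}

#' Refine change-point locations by local least squares
#'
#' The penalized fit spreads a boundary over a few probes (the jump is paid
#' for in pieces), so the single retained jump can sit slightly off the true
#' change point. For each retained change point this step scans a window of
#' candidate split positions between the neighbouring boundaries and keeps
#' the split minimizing the two-segment residual sum of squares of the
#' observed values — the exact least-squares location given the detected
#' breaks.
#'
#' @param jumps jump-set tibble of retained change points.
#' @param data the [signal_matrix()] being segmented.
#' @param window maximum displacement in probes (default 10).
#' @return The jump set with `j` relocated (sizes recomputed as the
#'   difference of the flanking segment means).
#' @export
refine_jumps <- function(jumps, data, window = 10L) {
  N <- ncol(data$values)
  purrr::map_dfr(unique(jumps$sequence), function(lab) {
    i <- match(lab, data$labels)
    own <- jumps[jumps$sequence == lab, , drop = FALSE]
    if (is.na(i) || nrow(own) == 0L) return(own)
    own <- own[order(own$j), , drop = FALSE]
    y <- data$values[i, ]
    js <- own$j
    for (u in seq_along(js)) {
      lb <- if (u == 1L) 1L else js[u - 1L]
      rb <- if (u == length(js)) N else js[u + 1L] - 1L
      lo <- max(lb + 1L, js[u] - window)
      hi <- min(rb, js[u] + window)
      cand <- lo:hi
      rss <- vapply(cand, function(jp) {
        a <- y[lb:(jp - 1L)]; b <- y[jp:rb]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        s <- 0
        if (length(a)) s <- s + sum((a - mean(a))^2)
        if (length(b)) s <- s + sum((b - mean(b))^2)
        if (length(a) == 0L || length(b) == 0L) s <- Inf
        s
      }, numeric(1))
      if (any(is.finite(rss))) js[u] <- cand[which.min(rss)]
    }
    own$j <- js
    own <- own[!duplicated(own$j), , drop = FALSE]
    # recompute sizes as differences of flanking observed means
    bounds <- c(1L, own$j, N + 1L)
    means <- vapply(seq_len(length(bounds) - 1L), function(u) {
      v <- y[bounds[u]:(bounds[u + 1L] - 1L)]
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    own$size <- diff(means)
    own
  })
}

#' Prune boundaries unsupported by the recomputed segment means
#'
#' After thresholding (and in particular after taking the union of change
#' points across signals), adjacent segments can differ by less than the
#' jump cutoff once their means are recomputed from the observed data. This
#' step removes, one at a time, the boundary whose recomputed mean difference
#' is furthest below the cutoff in every supporting sequence, until every
#' remaining boundary is supported by at least one sequence. Sequences with
#' no observations on one side of a boundary are uninformative for it.
#'
#' @param jumps jump-set tibble; the same boundaries may be shared by several
#'   sequences (a union), in which case support from any sequence retains a
#'   boundary for all.
#' @param data the [signal_matrix()] being segmented.
#' @param cutoffs named per-sequence cutoff vector (names = labels of `data`),
#'   e.g. `c * gamma_i` from the ruler.
#' @param shared if `TRUE` (default) boundaries are treated as shared across
#'   all sequences present in `jumps` (union semantics); if `FALSE` each
#'   sequence's jumps are pruned against its own cutoff only.
#' @return The pruned jump-set tibble.
#' @export
prune_jumps <- function(jumps, data, cutoffs, shared = TRUE) {
  N <- ncol(data$values)
  seg_mean <- function(i, from, to) {
    v <- data$values[i, from:to]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  prune_one <- function(js, rows) {
    js <- sort(unique(js))
    repeat {
      if (length(js) == 0L) break
      bounds <- c(1L, js, N + 1L)
      margin <- vapply(seq_along(js), function(u) {
        diffs <- vapply(rows, function(i) {
          a <- seg_mean(i, bounds[u], bounds[u + 1L] - 1L)
          b <- seg_mean(i, bounds[u + 1L], bounds[u + 2L] - 1L)
          if (is.na(a) || is.na(b)) return(NA_real_)
          abs(b - a) / cutoffs[[data$labels[i]]]
        }, numeric(1))
        if (all(is.na(diffs))) 0 else max(diffs, na.rm = TRUE)
      }, numeric(1))
      if (all(margin > 1)) break
      js <- js[-which.min(margin)]
    }
    js
  }
  if (shared) {
    rows <- match(unique(jumps$sequence), data$labels)
    rows <- rows[!is.na(rows)]
    js <- prune_one(unique(jumps$j), rows)
    jumps[jumps$j %in% js, , drop = FALSE]
  } else {
    purrr::map_dfr(unique(jumps$sequence), function(lab) {
      i <- match(lab, data$labels)
      own <- jumps[jumps$sequence == lab, , drop = FALSE]
      js <- prune_one(own$j, i)
      own[own$j %in% js, , drop = FALSE]
    })
  }
}

#' Union of change points across signals
#'
#' Combines the change points detected on several signals of the same sample
#' group (e.g. LRR and mBAF) into one finer segmentation: the union of all
#' change-point indices is applied to every sequence appearing in any of the
#' sets. Jump sizes are kept where a sequence contributed that change point
#' and are `NA` for imposed ones.
#'
#' @param jumpsets list of jump-set tibbles on the same probe grid.
#' @return A jump-set tibble (`sequence`, `j`, `size`).
#' @export
union_changepoints <- function(jumpsets) {
  all_j <- sort(unique(unlist(lapply(jumpsets, function(x) x$j))))
  seqs <- unique(unlist(lapply(jumpsets, function(x) unique(x$sequence))))
  empty <- tibble::tibble(sequence = character(), j = integer(), size = numeric())
  if (length(seqs) == 0L) return(empty)
  combined <- dplyr::bind_rows(jumpsets)
  out <- purrr::map_dfr(seqs, function(s) {
    own <- combined[combined$sequence == s, ]
    tibble::tibble(sequence = s, j = as.integer(all_j),
                   size = own$size[match(all_j, own$j)])
  })
  if (nrow(out) == 0L) empty else out
}

#' Two-stage segmentation of a GFL fit
#'
#' Convenience wrapper: extract jumps from a (laxly penalized) fit, threshold
#' them with the ruler heuristic or the modified BIC, and materialize the
#' segment table with means recomputed from the observed data.
#'
#' @param fit a `gfl_fit`.
#' @param sigma per-sequence noise SDs; default estimated from the data rows
#'   via [estimate_sigma()].
#' @param method `"ruler"` (default, used throughout the reference analyses)
#'   or `"mbic"`.
#' @param a,b,c ruler constants (see [ruler_threshold()]).
#' @param refine_window local boundary-refinement window ([refine_jumps()]);
#'   0 disables refinement.
#' @return Segment tibble (see [jumps_to_segments()]) with the retained jump
#'   set attached as attribute `"jumps"`.
#' @export
segment_gfl <- function(fit, sigma = NULL, method = c("ruler", "mbic"),
                        a = 1, b = 5, c = 0.2, refine_window = 10L) {
  method <- match.arg(method)
  data <- fit$data
  if (is.null(sigma)) {
    sigma <- vapply(seq_len(nrow(data$values)),
                    function(i) estimate_sigma(data$values[i, ]), numeric(1))
  }
  if (length(sigma) == 1L) sigma <- rep(sigma, nrow(data$values))
  names(sigma) <- data$labels
  cand <- collapse_jumps(extract_jumps(fit, sigma = sigma))
  kept <- if (method == "ruler") {
    ruler_threshold(cand, sigma, a = a, b = b, c = c)
  } else {
    purrr::map_dfr(data$labels, function(lab) {
      i <- match(lab, data$labels)
      own <- cand[cand$sequence == lab, ]
      keep_j <- mbic_threshold(data$values[i, ], own)
      own[own$j %in% keep_j, ]
    })
  }
  if (refine_window > 0L && nrow(kept) > 0L) {
    kept <- refine_jumps(kept, data, window = refine_window)
  }
  segs <- jumps_to_segments(kept, data, beta = fit$beta)
  attr(segs, "jumps") <- kept
  segs
}
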