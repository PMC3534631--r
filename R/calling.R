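#' Five-state BAF/LRR emission model
#'
#' Describes the typical Illumina-array signal patterns in copy-number states
#' `c = 0..4`. LRR in a state is normal around a state mean (in log2-ratio
#' units; the gain means are compressed by array saturation). BAF in states
#' 1-4 is a mixture over genotype clusters at centers `k/c` (`k` B alleles of
#' `c` copies) with binomial(`c`, `p_b`) weights, tight clusters near 0/1 and
#' broader heterozygote clusters, plus a small uniform outlier component; at
#' copy number 0 BAF carries no genotype information and is modelled as
#' uniform. Array clipping to \[0, 1\] is handled by censoring: values exactly
#' at 0 or 1 contribute cluster tail masses rather than densities, and the
#' uniform components reserve the `boundary_atom` share of their own mass at
#' each boundary so every state has positive likelihood at clipped values.
#'
#' @param lrr_mean length-5 LRR means for states 0..4.
#' @param p_b population B-allele frequency for cluster weights.
#' @param sd_homo,sd_het BAF cluster SDs near the 0/1 boundary and elsewhere.
#' @param outlier_frac mixture weight of the uniform BAF outlier component.
#' @param boundary_atom probability mass a uniform component places at each of
#'   the exact boundary values 0 and 1.
#' @return A `state_model` list, all parameters exposed.
#' @export
state_model <- function(lrr_mean = c(-3.0, -0.66, 0.0, 0.40, 0.68),
                        p_b = 0.5, sd_homo = 0.03, sd_het = 0.05,
                        outlier_frac = 0.01, boundary_atom = 0.01) {
  stopifnot(length(lrr_mean) == 5, p_b > 0, p_b < 1,
            sd_homo > 0, sd_het > 0,
            outlier_frac >= 0, outlier_frac < 1,
            boundary_atom > 0, boundary_atom < 0.5)
  structure(list(lrr_mean = lrr_mean, p_b = p_b, sd_homo = sd_homo,
                 sd_het = sd_het, outlier_frac = outlier_frac,
                 boundary_atom = boundary_atom),
            class = "state_model")
}

# BAF cluster centers and weights for a state (states 1..4).
baf_clusters <- function(state, model) {
  k <- 0:state
  centers <- k / state
  list(centers = centers,
       weights = stats::dbinom(k, state, model$p_b),
       sd = ifelse(centers %in% c(0, 1), model$sd_homo, model$sd_het))
}

# Per-observation BAF likelihood under a state: density on (0,1), mass at {0,1}.
baf_lik <- function(x, state, model) {
  atom <- model$boundary_atom
  unif <- ifelse(x <= 0 | x >= 1, atom, 1 - 2 * atom)  # uniform-type component
  if (state == 0) return(unif)
  cl <- baf_clusters(state, model)
  mix <- numeric(length(x))
  for (u in seq_along(cl$centers)) {
    mu <- cl$centers[u]; s <- cl$sd[u]
    contrib <- ifelse(
      x <= 0, stats::pnorm(0, mu, s),
      ifelse(x >= 1, stats::pnorm(1, mu, s, lower.tail = FALSE),
             stats::dnorm(x, mu, s))
    )
    mix <- mix + cl$weights[u] * contrib
  }
  (1 - model$outlier_frac) * mix + model$outlier_frac * unif
}

#' Log-likelihood of a segment under one copy-number state
#'
#' Sums the per-probe log BAF mixture likelihood and the log normal LRR
#' likelihood over the segment (probes are treated as independent, so
#' concatenating a segment with itself doubles the value). Missing entries
#' are dropped; an entirely empty segment is an error.
#'
#' @param baf BAF values of the segment's probes (untransformed, in \[0, 1\]).
#' @param lrr LRR values of the segment's probes.
#' @param state copy-number state in 0..4.
#' @param model a [state_model()].
#' @param sigma LRR noise SD of the sample (from [estimate_sigma()]).
#' @return Scalar log-likelihood.
#' @export
state_loglik <- function(baf, lrr, state, model = state_model(), sigma = 0.2) {
  if (!state %in% 0:4) stop("`state` must be in 0..4", call. = FALSE)
  baf <- baf[is.finite(baf)]
  lrr <- lrr[is.finite(lrr)]
  if (length(baf) == 0L && length(lrr) == 0L) {
    stop("empty segment: no observed BAF or LRR values", call. = FALSE)
  }
  ll <- 0
  if (length(baf) > 0L) {
    ll <- ll + sum(log(pmax(baf_lik(baf, state, model), 1e-300)))
  }
  if (length(lrr) > 0L) {
    ll <- ll + sum(stats::dnorm(lrr, model$lrr_mean[state + 1L], sigma, log = TRUE))
  }
  ll
}

#' Log-likelihood ratios of the non-diploid states against CN = 2
#'
#' `LR(c) = log L(x, y; c) - log L(x, y; 2)` for `c` in `{0, 1, 3, 4}`,
#' combining the BAF and LRR terms of [state_loglik()].
#'
#' @inheritParams state_loglik
#' @return Named numeric vector `c("0", "1", "3", "4")`.
#' @export
likelihood_ratio <- function(baf, lrr, model = state_model(), sigma = 0.2) {
  ref <- state_loglik(baf, lrr, 2L, model, sigma)
  vapply(c(0L, 1L, 3L, 4L),
         function(s) state_loglik(baf, lrr, s, model, sigma) - ref,
         numeric(1)) |> setNames(c("0", "1", "3", "4"))
}

#' Acceptance thresholds for copy-number calls
#'
#' @param r1 log-likelihood-ratio acceptance cutoff (default 10).
#' @param r2_dup,r2_del minimum absolute segment LRR mean, in units of the
#'   sample noise SD, for duplication and deletion calls (defaults 1 and 1.5).
#'   This guard stops long segments whose LRR has a small non-zero mean from
#'   experimental artifacts from being miscalled on likelihood ratio alone.
#' @return A `calling_config` list.
#' @export
calling_config <- function(r1 = 10, r2_dup = 1, r2_del = 1.5) {
  stopifnot(!is.na(r1), r2_dup >= 0, r2_del >= 0)
  structure(list(r1 = r1, r2_dup = r2_dup, r2_del = r2_del),
            class = "calling_config")
}

# Deterministic argmax order: prefer states closer to CN=2, deletion on tie.
state_preference <- c(1L, 3L, 0L, 4L)

#' Call the copy-number state of one segment
#'
#' Picks the state maximizing LR (ties broken toward the state closer to 2,
#' and toward the deletion on an exact-distance tie), then accepts it only if
#' `LR > r1` and the absolute segment LRR mean exceeds `r2 * sigma` (`r2_dup`
#' for gains, `r2_del` for losses). A rejected segment is reported as CN = 2
#' with the reason.
#'
#' @inheritParams state_loglik
#' @param cfg a [calling_config()].
#' @return One-row tibble: `state`, `lr` (of the argmax state), `lr_0`,
#'   `lr_1`, `lr_3`, `lr_4`, `lrr_mean`, `accepted`, `reason`
#'   (`"none"`, `"lr_below_r1"` or `"mean_shift_below_r2"`).
#' @export
call_segment <- function(baf, lrr, model = state_model(),
                         cfg = calling_config(), sigma = 0.2) {
  lrs <- likelihood_ratio(baf, lrr, model, sigma)
  ord <- as.character(state_preference)
  best <- ord[which.max(lrs[ord])]
  chat <- as.integer(best)
  lrr_obs <- lrr[is.finite(lrr)]
  ybar <- if (length(lrr_obs)) mean(lrr_obs) else 0
  r2 <- if (chat >= 3) cfg$r2_dup else cfg$r2_del
  reason <- "none"
  if (lrs[[best]] <= cfg$r1) {
    reason <- "lr_below_r1"
  } else if (abs(ybar) <= r2 * sigma) {
    reason <- "mean_shift_below_r2"
  }
  accepted <- reason == "none"
  tibble::tibble(
    state = if (accepted) chat else 2L,
    lr = unname(lrs[[best]]),
    lr_0 = unname(lrs[["0"]]), lr_1 = unname(lrs[["1"]]),
    lr_3 = unname(lrs[["3"]]), lr_4 = unname(lrs[["4"]]),
    lrr_mean = ybar, accepted = accepted, reason = reason
  )
}

#' Call copy-number states for a segment table
#'
#' Applies [call_segment()] to every row of a segment table, looking up each
#' sample's BAF and LRR values over the segment's probe range. Calling is
#' per sample even when segmentation was joint.
#'
#' @param segments segment tibble from [segment_gfl()] / [jumps_to_segments()].
#' @param lrr a [signal_matrix()] of LRR values (labels match
#'   `segments$sequence`).
#' @param baf optional matching [signal_matrix()] of untransformed BAF values.
#' @param model a [state_model()].
#' @param cfg a [calling_config()].
#' @param sigma per-sample LRR noise SD, named vector or scalar; default
#'   estimated per sample with [estimate_sigma()].
#' @return `segments` with the [call_segment()] columns appended (one output
#'   row per input segment, accepted or not).
#' @export
call_segments <- function(segments, lrr, baf = NULL, model = state_model(),
                          cfg = calling_config(), sigma = NULL) {
  stopifnot(inherits(lrr, "signal_matrix"))
  if (is.null(sigma)) {
    sigma <- vapply(seq_along(lrr$labels),
                    function(i) estimate_sigma(lrr$values[i, ]), numeric(1))
    names(sigma) <- lrr$labels
  } else if (is.null(names(sigma))) {
    sigma <- setNames(rep_len(sigma, length(lrr$labels)), lrr$labels)
  }
  calls <- purrr::map_dfr(seq_len(nrow(segments)), function(r) {
    seg <- segments[r, ]
    i <- match(seg$sequence, lrr$labels)
    if (is.na(i)) stop("sample '", seg$sequence, "' not found in LRR signals", call. = FALSE)
    idx <- seg$start:seg$end
    y <- lrr$values[i, idx]
    x <- if (!is.null(baf)) {
      ib <- match(seg$sequence, baf$labels)
      baf$values[ib, idx]
    } else numeric(0)
    call_segment(x, y, model, cfg, sigma[[seg$sequence]])
  })
  dplyr::bind_cols(segments, calls)
}
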