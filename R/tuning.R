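#' Relative weight of the fused versus group-fused penalty
#'
#' `rho(p)` regulates how the fusion budget is split between the per-sequence
#' total-variation penalty (weight `rho`) and the group penalty on shared
#' jumps (weight `1 - rho`), where `p` is the proportion of the M sequences
#' expected to carry the same CNV. The endpoints are fixed by the design —
#' fully shared signals (`p = 1`, e.g. LRR and mBAF of one subject) want
#' `rho = 0`, enforcing jumps at identical places; completely unrelated
#' sequences (`p = 0`) want `rho = 1` — and the default is the linear
#' interpolant `rho(p) = 1 - p` (e.g. `p = 1/2` for a parent-offspring pair).
#'
#' @param p expected sharing proportion in \[0, 1\].
#' @return Weight in \[0, 1\], non-increasing in `p`.
#' @export
rho_weight <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  1 - p
}

#' Default penalty parameters from data scale and sharing proportion
#'
#' Implements the tuning guidelines
#' \deqn{\lambda_{1,i} = c_1\hat\sigma_i,\quad
#'   \lambda_{2,i} = \rho(p)\, c_2 \hat\sigma_i \sqrt{\log N},\quad
#'   \lambda_{3,i} = [1-\rho(p)]\, c_3 \hat\sigma_i \sqrt{p M \log N}.}
#' Penalties scale with the per-sequence noise level (so unit-normalized
#' signals share one set of penalties), the fusion penalties carry the
#' `sqrt(log N)` multiple-comparison rate over the N-1 candidate jumps, and
#' the group penalty additionally grows like the square root of the expected
#' number `pM` of carriers, as in the original group-lasso proposal. The
#' lasso term needs no `log N` factor: it acts as a soft threshold on the
#' already low-dimensional fused solution.
#'
#' @param sigma per-sequence noise SD estimates (length M or scalar), e.g.
#'   from [estimate_sigma()].
#' @param N number of probes (candidate jumps N - 1).
#' @param M number of sequences; default `length(sigma)`.
#' @param p expected proportion of sequences sharing a CNV, in \[0, 1\].
#' @param c1,c2,c3 positive multipliers; defaults `c1 = 0.1` (so
#'   `lambda1 = 0.1` on unit-variance signals), `c2 = c3 = 1`. Adjust for
#'   unusual signal-to-noise ratios or CNV sizes.
#' @param rho sharing-weight function; default [rho_weight()].
#' @param ... further arguments (e.g. `epsilon`, `tol`, `max_iter`,
#'   `fusion_weights`) passed to [penalty_config()].
#' @return A [penalty_config()] with sequence-specific penalties.
#' @export
#' @examples
#' default_penalties(sigma = 0.25, N = 2000, M = 20, p = 0.3)
default_penalties <- function(sigma, N, M = length(sigma), p = 0,
                              c1 = 0.1, c2 = 1, c3 = 1, rho = rho_weight, ...) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  if (N < 2) stop("`N` must be >= 2", call. = FALSE)
  if (M < 1) stop("`M` must be >= 1", call. = FALSE)
  if (any(c(c1, c2, c3) <= 0)) stop("multipliers c1, c2, c3 must be > 0", call. = FALSE)
  if (length(sigma) == 1L) sigma <- rep(sigma, M)
  if (length(sigma) != M) stop("`sigma` must be scalar or length M", call. = FALSE)
  r <- rho(p)
  penalty_config(
    lambda1 = c1 * sigma,
    lambda2 = r * c2 * sigma * sqrt(log(N)),
    lambda3 = (1 - r) * c3 * sigma * sqrt(p * M * log(N)),
    ...
  )
}
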