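#' Penalty configuration for the generalized fused lasso
#'
#' The generalized fused lasso objective for an M x N signal matrix Y is
#' \deqn{f(\beta) = \tfrac12 \sum_{ij} \delta_{ij}(y_{ij}-\beta_{ij})^2
#'   + \sum_i \lambda_{1,i} \sum_j |\beta_{ij}|
#'   + \sum_i \lambda_{2,i} \sum_{j\ge2} |\beta_{ij}-\beta_{i,j-1}|
#'   + \sum_{j\ge2} \|\lambda_3 * (\beta_{(j)}-\beta_{(j-1)})\|_2,}
#' a goodness-of-fit term restricted to observed entries plus a sparsity
#' (lasso) penalty pulling means to the diploid baseline 0, a per-sequence
#' total-variation penalty favouring few jumps, and a Euclidean group penalty
#' on each column of jumps favouring change points shared across sequences
#' (`*` is entry-wise multiplication, so heterogeneous `lambda3` are allowed).
#' For optimization the absolute values and the Euclidean norm are smoothed as
#' `|x| -> sqrt(x^2 + eps)` and `||x|| -> sqrt(||x||^2 + eps)`.
#'
#' @param lambda1,lambda2,lambda3 non-negative penalty multipliers, each a
#'   scalar or a length-M vector (recycled across sequences at fit time).
#' @param epsilon smoothing constant `eps > 0`; the default `1e-8` keeps the
#'   smoothing bias (about `sqrt(eps)`) far below any meaningful jump on
#'   signals normalized to unit noise while preserving conditioning.
#' @param tol relative decrease of the smoothed objective below which the MM
#'   iteration stops.
#' @param beta_tol alternative stop: maximum absolute change of beta.
#' @param max_iter iteration cap; non-convergence yields a warning, not an error.
#' @param fusion_weights optional length `N-1` non-negative multipliers making
#'   the fusion penalties location specific (e.g. down-weighting known
#'   copy-number-polymorphism regions); default all ones.
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0,
                           epsilon = 1e-8, tol = 1e-6, beta_tol = 1e-6,
                           max_iter = 500L, fusion_weights = NULL) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) stop("penalties must be >= 0", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (tol <= 0 || beta_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (!is.null(fusion_weights) && any(fusion_weights < 0)) {
    stop("`fusion_weights` must be >= 0", call. = FALSE)
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 epsilon = epsilon, tol = tol, beta_tol = beta_tol,
                 max_iter = as.integer(max_iter), fusion_weights = fusion_weights),
            class = "penalty_config")
}

#' @export
print.penalty_config <- function(x, ...) {
  fmt <- function(v) if (length(v) > 4) paste0(paste(signif(v[1:4], 4), collapse = ", "), ", ...")
                     else paste(signif(v, 4), collapse = ", ")
  cat("<penalty_config>\n",
      "  lambda1: ", fmt(x$lambda1), "\n",
      "  lambda2: ", fmt(x$lambda2), "\n",
      "  lambda3: ", fmt(x$lambda3), "\n",
      sprintf("  epsilon: %g  tol: %g  max_iter: %d\n", x$epsilon, x$tol, x$max_iter),
      sep = "")
  invisible(x)
}

# Expand scalar/length-M penalty vectors and fusion weights for an M x N problem.
expand_config <- function(cfg, M, N) {
  rec <- function(v, what) {
    if (length(v) == 1L) rep(v, M)
    else if (length(v) == M) as.numeric(v)
    else stop("`", what, "` must be scalar or length M", call. = FALSE)
  }
  w <- cfg$fusion_weights
  if (is.null(w)) w <- rep(1, max(N - 1L, 0L))
  if (length(w) != N - 1L) stop("`fusion_weights` must have length N - 1", call. = FALSE)
  list(l1 = rec(cfg$lambda1, "lambda1"), l2 = rec(cfg$lambda2, "lambda2"),
       l3 = rec(cfg$lambda3, "lambda3"), w = w, eps = cfg$epsilon)
}

#' Generalized fused lasso objective
#'
#' Evaluates the GFL objective (see [penalty_config()]) at `beta`, either with
#' the exact l1/l2 norms or with their eps-smoothed versions used by the
#' solver. Masked entries of the data contribute nothing to the fit term; all
#' entries of `beta` enter the penalties. When every `lambda3` is zero the
#' group term is dropped entirely (avoiding a spurious `sqrt(eps)` constant
#' per column in the smoothed version).
#'
#' @param beta M x N matrix of means.
#' @param data a [signal_matrix()].
#' @param cfg a [penalty_config()].
#' @param smoothed use the eps-smoothed norms (default `FALSE`).
#' @return Scalar objective value.
#' @export
gfl_objective <- function(beta, data, cfg, smoothed = FALSE) {
  beta <- as.matrix(beta)
  M <- nrow(data$values); N <- ncol(data$values)
  if (!all(dim(beta) == c(M, N))) stop("`beta` must be M x N", call. = FALSE)
  p <- expand_config(cfg, M, N)
  eps <- if (smoothed) p$eps else 0
  h <- function(x) sqrt(x^2 + eps)
  y0 <- ifelse(data$mask == 1, data$values, 0)
  fit <- 0.5 * sum(data$mask * (y0 - beta)^2)
  lasso <- sum(p$l1 * rowSums(h(beta)))
  if (N >= 2) {
    d <- beta[, 2:N, drop = FALSE] - beta[, 1:(N - 1), drop = FALSE]
    tv <- sum(p$l2 * (h(d) %*% p$w))
    if (any(p$l3 > 0)) {
      gr <- sum(p$w * sqrt(colSums((p$l3 * d)^2) + eps))
    } else gr <- 0
  } else tv <- gr <- 0
  fit + lasso + tv + gr
}

#' Build the quadratic MM surrogate at the current iterate
#'
#' Majorizes the smoothed objective at `beta_m` using the concavity of the
#' square root, `sqrt(x^2+eps) <= (x^2+eps)/(2w) + w/2` with
#' `w = sqrt(z^2+eps)` (and its vector analogue for the group term). The
#' surrogate separates over sequence rows into quadratics
#' `g_i(b) = 1/2 b' A_i b - b_i' b + const` with each `A_i` symmetric
#' tridiagonal positive definite; data terms enter only where the mask is 1.
#' Positions with no data and all-zero penalties are pinned to their current
#' value (unit diagonal) so the system stays non-singular.
#'
#' @param beta_m M x N current iterate (finite).
#' @param data a [signal_matrix()].
#' @param cfg a [penalty_config()].
#' @return A `surrogate_system`: list with M x N `diag`, M x (N-1) `offdiag`,
#'   M x N `rhs`, and the additive `constant` making the surrogate tangent to
#'   the smoothed objective at `beta_m`.
#' @export
build_surrogate <- function(beta_m, data, cfg) {
  beta_m <- as.matrix(beta_m)
  M <- nrow(data$values); N <- ncol(data$values)
  if (!all(dim(beta_m) == c(M, N))) stop("`beta_m` must be M x N", call. = FALSE)
  if (!all(is.finite(beta_m))) stop("`beta_m` must be finite", call. = FALSE)
  p <- expand_config(cfg, M, N)
  eps <- p$eps
  delta <- data$mask
  y0 <- ifelse(delta == 1, data$values, 0)

  w1 <- sqrt(beta_m^2 + eps)                       # M x N
  u1 <- p$l1 / w1                                  # lasso curvature
  constant <- sum(p$l1 * rowSums(eps / (2 * w1) + w1 / 2))
  if (N >= 2) {
    d <- beta_m[, 2:N, drop = FALSE] - beta_m[, 1:(N - 1), drop = FALSE]
    w2 <- sqrt(d^2 + eps)                          # M x (N-1)
    u2 <- sweep(p$l2 / w2, 2, p$w, `*`)
    constant <- constant + sum(p$l2 * ((eps / (2 * w2) + w2 / 2) %*% p$w))
    if (any(p$l3 > 0)) {
      W3 <- sqrt(colSums((p$l3 * d)^2) + eps)      # length N-1
      u3 <- outer(p$l3^2, p$w / W3)
      constant <- constant + sum(p$w * (eps / (2 * W3) + W3 / 2))
    } else u3 <- matrix(0, M, N - 1)
    couple <- u2 + u3                              # off-diagonal magnitude
  } else couple <- matrix(0, M, 0)
  diagA <- delta + u1
  if (N >= 2) {
    diagA[, 2:N] <- diagA[, 2:N] + couple
    diagA[, 1:(N - 1)] <- diagA[, 1:(N - 1)] + couple
  }
  rhs <- delta * y0
  # pin fully unconstrained coordinates (no data, no penalty) to beta_m
  free <- diagA == 0
  if (any(free)) {
    diagA[free] <- 1
    rhs[free] <- beta_m[free]
  }
  constant <- constant + 0.5 * sum(delta * y0^2)
  structure(list(diag = diagA, offdiag = -couple, rhs = rhs, constant = constant),
            class = "surrogate_system")
}

#' Evaluate a surrogate system at a candidate beta
#'
#' Returns `sum_i 1/2 b_i' A_i b_i - rhs_i' b_i` plus the tangency constant,
#' i.e. the value of the majorizing function; at the expansion point it equals
#' the smoothed objective, and everywhere else it lies above it.
#'
#' @param sys a `surrogate_system` from [build_surrogate()].
#' @param beta M x N matrix.
#' @return Scalar surrogate value.
#' @export
surrogate_value <- function(sys, beta) {
  beta <- as.matrix(beta)
  N <- ncol(sys$diag)
  quad <- 0.5 * sum(sys$diag * beta^2)
  if (N >= 2) {
    quad <- quad + sum(sys$offdiag * beta[, 1:(N - 1), drop = FALSE] *
                         beta[, 2:N, drop = FALSE])
  }
  quad - sum(sys$rhs * beta) + sys$constant
}

#' Solve the per-row tridiagonal systems of an MM surrogate
#'
#' Applies the Thomas (tridiagonal matrix) algorithm independently to each
#' sequence row: `A_i x_i = b_i` with `A_i` SPD tridiagonal, in O(N) per row
#' without pivoting. This is the entire per-iteration cost of the MM solver,
#' O(MN) overall.
#'
#' @param sys a `surrogate_system` (or any list with matrices `diag`,
#'   `offdiag`, `rhs` of shapes M x N, M x (N-1), M x N).
#' @return M x N matrix of row-wise solutions.
#' @export
solve_tridiagonal <- function(sys) {
  off <- sys$offdiag
  if (ncol(sys$diag) == 1L) off <- matrix(0, nrow(sys$diag), 0)
  .thomas_solve_rows(sys$diag, off, sys$rhs)
}

#' Fit the generalized fused lasso by majorization-minimization
#'
#' Iterates [build_surrogate()] / [solve_tridiagonal()] from `beta0` until the
#' relative decrease of the smoothed objective falls below `cfg$tol` or the
#' iterate moves by less than `cfg$beta_tol`, whichever first. Each step
#' minimizes a tangent majorizer exactly, so the smoothed objective is
#' non-increasing along the trace. Masked entries of the fit are finite and
#' determined by the fusion penalties from neighbouring observed probes.
#'
#' @param data a [signal_matrix()].
#' @param cfg a [penalty_config()].
#' @param beta0 optional M x N start; default: observed values where measured,
#'   0 elsewhere (the unpenalized fit).
#' @return A `gfl_fit` object: list with `beta` (M x N fitted means),
#'   `objective_trace` (smoothed objective, first entry at `beta0`),
#'   `n_iter`, `converged`, plus the `data` and `cfg` used.
#' @export
#' @examples
#' y <- c(rnorm(30), rnorm(30, 1))
#' sm <- signal_matrix(rbind(y), chrom = "1", positions = seq_along(y))
#' fit <- fit_gfl(sm, penalty_config(lambda2 = 2))
#' plot(y); lines(fit$beta[1, ], col = 2, lwd = 2)
fit_gfl <- function(data, cfg = penalty_config(), beta0 = NULL) {
  stopifnot(inherits(data, "signal_matrix"))
  M <- nrow(data$values); N <- ncol(data$values)
  if (is.null(beta0)) {
    beta0 <- ifelse(data$mask == 1, data$values, 0)
  } else {
    beta0 <- as.matrix(beta0)
    if (!all(dim(beta0) == c(M, N))) stop("`beta0` must be M x N", call. = FALSE)
  }
  beta <- beta0
  f <- gfl_objective(beta, data, cfg, smoothed = TRUE)
  trace <- f
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    sys <- build_surrogate(beta, data, cfg)
    beta_new <- solve_tridiagonal(sys)
    f_new <- gfl_objective(beta_new, data, cfg, smoothed = TRUE)
    trace <- c(trace, f_new)
    dbeta <- max(abs(beta_new - beta))
    rel <- (f - f_new) / max(abs(f), 1e-300)
    beta <- beta_new
    f <- f_new
    if (dbeta < cfg$beta_tol || (rel >= 0 && rel < cfg$tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MM solver did not converge in ", cfg$max_iter, " iterations", call. = FALSE)
  }
  structure(list(beta = beta, objective_trace = trace, n_iter = iter,
                 converged = converged, data = data, cfg = cfg),
            class = "gfl_fit")
}

#' @export
print.gfl_fit <- function(x, ...) {
  cat(sprintf("<gfl_fit> %d x %d, %d MM iteration%s, objective %.6g (%s)\n",
              nrow(x$beta), ncol(x$beta), x$n_iter, if (x$n_iter == 1) "" else "s",
              tail(x$objective_trace, 1),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a GFL fit into a long tibble
#'
#' @param x a `gfl_fit`.
#' @param ... unused.
#' @return Tibble with `sequence`, `chrom`, `position`, `value` (observed, `NA`
#'   where masked) and `fitted` (the piecewise-constant mean estimate).
#' @export
tidy.gfl_fit <- function(x, ...) {
  out <- tidy.signal_matrix(x$data)
  out$fitted <- as.vector(x$beta)
  out
}

#' One-row summary of a GFL fit
#'
#' @param x a `gfl_fit`.
#' @param ... unused.
#' @return Tibble with sizes, iteration count, convergence flag and the final
#'   smoothed objective.
#' @export
glance.gfl_fit <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x$beta), n_probes = ncol(x$beta),
    n_iter = x$n_iter, converged = x$converged,
    objective = tail(x$objective_trace, 1)
  )
}

#' Plot fitted means over the observed signals
#'
#' @param object a `gfl_fit`.
#' @param ... unused.
#' @return A ggplot: one facet per sequence, points = observed values,
#'   line = fitted piecewise-constant mean.
#' @export
autoplot.gfl_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.3, alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~sequence, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = sprintf("position (chr%s)", object$data$chrom), y = "signal")
}
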