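# Shared fixtures: all synthetic, built in code at test time.

# Random fully observed signal matrix.
random_sm <- function(M, N, sd = 1) {
  signal_matrix(matrix(rnorm(M * N, sd = sd), M, N),
                chrom = "1", positions = seq_len(N))
}

# Analytic gradient of the eps-smoothed GFL objective; used to drive the
# general-purpose optimizer that serves as the independent oracle for the MM
# solver. Kept free of any solver code path.
smoothed_gradient <- function(v, sm, cfg) {
  M <- nrow(sm$values); N <- ncol(sm$values)
  beta <- matrix(v, M, N)
  eps <- cfg$epsilon
  l1 <- rep_len(cfg$lambda1, M)
  l2 <- rep_len(cfg$lambda2, M)
  l3 <- rep_len(cfg$lambda3, M)
  y0 <- ifelse(sm$mask == 1, sm$values, 0)
  g <- sm$mask * (beta - y0) + l1 * beta / sqrt(beta^2 + eps)
  if (N >= 2) {
    d <- beta[, 2:N, drop = FALSE] - beta[, 1:(N - 1), drop = FALSE]
    t2 <- l2 * d / sqrt(d^2 + eps)
    W <- sqrt(colSums((l3 * d)^2) + eps)
    t3 <- sweep(l3^2 * d, 2, W, "/")
    g[, 2:N] <- g[, 2:N] + t2 + t3
    g[, 1:(N - 1)] <- g[, 1:(N - 1)] - t2 - t3
  }
  as.vector(g)
}

# Independent minimizer of the smoothed objective (L-BFGS-B with analytic
# gradient), started at the data.
oracle_minimum <- function(sm, cfg) {
  M <- nrow(sm$values); N <- ncol(sm$values)
  start <- as.vector(ifelse(sm$mask == 1, sm$values, 0))
  o <- optim(start,
             fn = function(v) gfl_objective(matrix(v, M, N), sm, cfg, smoothed = TRUE),
             gr = function(v) smoothed_gradient(v, sm, cfg),
             method = "L-BFGS-B",
             control = list(maxit = 20000, factr = 1e1))
  o
}

# Long signal tibble from a generator result, as the pipeline consumes it.
sim_to_long <- function(sim) {
  lrr <- dplyr::rename(tidy(sim$lrr), lrr = "value", sample = "sequence")
  baf <- dplyr::rename(tidy(sim$baf), baf = "value", sample = "sequence")
  dplyr::left_join(lrr, baf[, c("sample", "position", "baf")],
                   by = c("sample", "position"))
}

# Random SPD tridiagonal system in surrogate form (diagonally dominant).
random_spd_tridiag <- function(M, N) {
  off <- matrix(rnorm(M * (N - 1)), M, N - 1)
  diag <- matrix(runif(M * N, 0.1, 1), M, N)
  diag[, 1:(N - 1)] <- diag[, 1:(N - 1)] + abs(off)
  diag[, 2:N] <- diag[, 2:N] + abs(off)
  list(diag = diag, offdiag = off, rhs = matrix(rnorm(M * N), M, N), constant = 0)
}

# BAF/LRR segment values drawn from a state's own emission model.
segment_from_state <- function(state, n, model = state_model(), lrr_sd = 0.2) {
  g <- rbinom(n, 2, model$p_b)
  ns <- noise_spec(lrr_sd = lrr_sd, baf_sd_het = model$sd_het,
                   baf_sd_homo = model$sd_homo,
                   outlier_frac = model$outlier_frac)
  baf <- if (state == 0) runif(n) else {
    b <- gflcnv:::draw_b_count(g, state)
    gflcnv:::draw_baf(b / state, ns)
  }
  list(baf = baf, lrr = rnorm(n, model$lrr_mean[state + 1], lrr_sd))
}
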