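test_that("objective matches hand arithmetic and exact limits", {
  sm <- signal_matrix(rbind(c(0, 2)), chrom = "1", positions = 1:2)
  cfg <- penalty_config(lambda1 = 1, lambda2 = 1, lambda3 = 0)
  # fit 1/2(1 + 1) + lasso 1*(1 + 1) + fusion 1*0
  expect_equal(gfl_objective(rbind(c(1, 1)), sm, cfg, smoothed = FALSE), 3)

  # perfect fit, no penalties
  set.seed(1)
  sm2 <- random_sm(2, 8)
  expect_equal(gfl_objective(sm2$values, sm2, penalty_config(), smoothed = FALSE), 0)

  # smoothed penalties approach the exact value from above
  cfg3 <- penalty_config(lambda1 = 0.5, lambda2 = 1, lambda3 = 0.8, epsilon = 1e-4)
  beta <- matrix(rnorm(16), 2, 8)
  expect_gte(gfl_objective(beta, sm2, cfg3, smoothed = TRUE),
             gfl_objective(beta, sm2, cfg3, smoothed = FALSE))
  cfg4 <- penalty_config(lambda1 = 0.5, lambda2 = 1, lambda3 = 0.8, epsilon = 1e-12)
  expect_equal(gfl_objective(beta, sm2, cfg4, smoothed = TRUE),
               gfl_objective(beta, sm2, cfg4, smoothed = FALSE),
               tolerance = 1e-5)
  expect_error(gfl_objective(matrix(0, 3, 3), sm2, cfg3), "M x N")
})

test_that("surrogate is tangent at the expansion point and majorizes elsewhere", {
  set.seed(21)
  for (rep in 1:5) {
    M <- sample(1:3, 1); N <- sample(5:20, 1)
    sm <- random_sm(M, N)
    cfg <- penalty_config(lambda1 = runif(1, 0, 0.5), lambda2 = runif(1, 0, 2),
                          lambda3 = runif(1, 0, 2), epsilon = 10^runif(1, -8, -4))
    bm <- matrix(rnorm(M * N), M, N)
    sys <- build_surrogate(bm, sm, cfg)
    f_m <- gfl_objective(bm, sm, cfg, smoothed = TRUE)
    expect_lt(abs(surrogate_value(sys, bm) - f_m), 1e-10)
    for (k in 1:20) {
      b <- bm + matrix(rnorm(M * N, sd = runif(1, 0.1, 3)), M, N)
      expect_gte(surrogate_value(sys, b) - gfl_objective(b, sm, cfg, smoothed = TRUE),
                 -1e-10)
    }
  }
})

test_that("surrogate has no off-diagonal coupling without fusion penalties", {
  set.seed(3)
  sm <- random_sm(2, 10)
  sys <- build_surrogate(sm$values, sm, penalty_config(lambda1 = 0.7))
  expect_true(all(sys$offdiag == 0))
})

test_that("tridiagonal solve is exact", {
  # identity system
  sys <- list(diag = matrix(1, 2, 4), offdiag = matrix(0, 2, 3),
              rhs = matrix(1:8, 2, 4))
  expect_equal(solve_tridiagonal(sys), matrix(1:8, 2, 4), ignore_attr = TRUE)

  # 2x2 hand solve: [[2,1],[1,2]] x = (1,1) -> (1/3, 1/3)
  sys2 <- list(diag = rbind(c(2, 2)), offdiag = rbind(1), rhs = rbind(c(1, 1)))
  expect_equal(solve_tridiagonal(sys2), rbind(c(1 / 3, 1 / 3)), tolerance = 1e-14)

  # random SPD systems against a dense solve
  set.seed(7)
  for (rep in 1:5) {
    sys3 <- random_spd_tridiag(3, 50)
    x <- solve_tridiagonal(sys3)
    for (i in 1:3) {
      A <- diag(sys3$diag[i, ])
      for (j in 1:49) A[j, j + 1] <- A[j + 1, j] <- sys3$offdiag[i, j]
      dense <- solve(A, sys3$rhs[i, ])
      expect_lt(max(abs(x[i, ] - dense)) / max(abs(dense)), 1e-10)
    }
  }

  sys_bad <- list(diag = rbind(c(1, NA)), offdiag = rbind(0), rhs = rbind(c(1, 1)))
  expect_error(solve_tridiagonal(sys_bad), "non-finite")
})

test_that("unpenalized fit returns the data in one iteration", {
  set.seed(5)
  sm <- random_sm(2, 30)
  fit <- fit_gfl(sm, penalty_config())
  expect_identical(fit$beta, sm$values)
  expect_identical(fit$n_iter, 1L)
  expect_true(fit$converged)
})

test_that("dominant penalties drive the fit to their closed-form limits", {
  set.seed(6)
  y <- rnorm(40)
  sm <- signal_matrix(rbind(y), chrom = "1", positions = 1:40)
  # huge lasso: everything shrinks to (numerically) zero
  fit1 <- fit_gfl(sm, penalty_config(lambda1 = 10 * max(abs(y)) * 40,
                                     epsilon = 1e-10, max_iter = 2000))
  expect_lt(max(abs(fit1$beta)), 1e-4)
  # huge fusion, single sequence: constant at the mean
  fit2 <- fit_gfl(sm, penalty_config(lambda2 = 1e5, epsilon = 1e-10,
                                     tol = 1e-12, beta_tol = 1e-9, max_iter = 5000))
  expect_equal(as.vector(fit2$beta), rep(mean(y), 40), tolerance = 1e-4)
})

test_that("MM matches an independent numerical minimizer on random instances", {
  set.seed(8)
  for (rep in 1:10) {
    M <- sample(1:3, 1); N <- sample(5:30, 1)
    sm <- random_sm(M, N)
    cfg <- penalty_config(lambda1 = runif(1, 0, 0.5), lambda2 = runif(1, 0, 2),
                          lambda3 = runif(1, 0, 2),
                          tol = 1e-12, beta_tol = 1e-10, max_iter = 3000)
    fit <- suppressWarnings(fit_gfl(sm, cfg))
    o <- oracle_minimum(sm, cfg)
    f_mm <- tail(fit$objective_trace, 1)
    expect_lt(abs(f_mm - o$value) / abs(o$value), 1e-4)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("fitted rows permute with the sequences", {
  set.seed(9)
  sm <- random_sm(3, 25)
  cfg <- penalty_config(lambda1 = 0.1, lambda2 = 0.8, lambda3 = 1.2)
  fit <- fit_gfl(sm, cfg)
  perm <- c(3, 1, 2)
  smp <- signal_matrix(sm$values[perm, ], chrom = sm$chrom,
                       positions = sm$positions, labels = sm$labels[perm])
  fitp <- fit_gfl(smp, cfg)
  expect_equal(fitp$beta, fit$beta[perm, ], tolerance = 1e-10)
})

test_that("solution scales with the data when penalties and smoothing scale along", {
  set.seed(10)
  sm <- random_sm(2, 20)
  cfg <- penalty_config(lambda1 = 0.2, lambda2 = 1, lambda3 = 0.5, epsilon = 1e-9,
                        tol = 1e-10, beta_tol = 1e-9, max_iter = 2000)
  fit <- fit_gfl(sm, cfg)
  s <- 3.7
  sms <- signal_matrix(s * sm$values, chrom = "1", positions = sm$positions)
  cfgs <- penalty_config(lambda1 = s * 0.2, lambda2 = s * 1, lambda3 = s * 0.5,
                         epsilon = s^2 * 1e-9, tol = 1e-10, beta_tol = s * 1e-9,
                         max_iter = 2000)
  fits <- fit_gfl(sms, cfgs)
  # the stopping rule truncates the two runs at slightly different iterates
  expect_equal(fits$beta, s * fit$beta, tolerance = 1e-3)
})

test_that("masked positions are interpolated within their fitted neighbors", {
  set.seed(12)
  v <- matrix(rnorm(2 * 30), 2, 30)
  v[1, c(5, 6, 14)] <- NA
  v[2, c(1, 30)] <- NA
  sm <- signal_matrix(v, chrom = "1", positions = 1:30)
  fit <- fit_gfl(sm, penalty_config(lambda2 = 1, lambda3 = 0.5,
                                    tol = 1e-10, beta_tol = 1e-9, max_iter = 2000))
  for (i in 1:2) {
    for (j in which(sm$mask[i, ] == 0)) {
      nb <- c(if (j > 1) fit$beta[i, j - 1], if (j < 30) fit$beta[i, j + 1])
      expect_gte(fit$beta[i, j], min(nb) - 1e-8)
      expect_lte(fit$beta[i, j], max(nb) + 1e-8)
    }
  }
  expect_true(all(is.finite(fit$beta)))
})

test_that("solver cost grows about linearly with problem size", {
  set.seed(13)
  time_solve <- function(N) {
    sys <- random_spd_tridiag(2, N)
    reps <- max(1L, as.integer(2e5 / N))
    t0 <- Sys.time()
    for (r in seq_len(reps)) solve_tridiagonal(sys)
    as.numeric(Sys.time() - t0, units = "secs") / reps
  }
  t_small <- time_solve(1e3)
  t_big <- time_solve(1e5)
  # 100x the size should cost far less than quadratic scaling would imply
  expect_lt(t_big / max(t_small, 1e-9), 100 * 20)
})

test_that("non-convergence warns and reports converged = FALSE", {
  set.seed(14)
  sm <- random_sm(1, 50)
  expect_warning(
    fit <- fit_gfl(sm, penalty_config(lambda2 = 2, tol = 1e-15, beta_tol = 1e-15,
                                      max_iter = 3L)),
    "did not converge")
  expect_false(fit$converged)
  expect_length(fit$objective_trace, 4L)
})
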