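test_that("jumps are the above-floor first differences", {
  beta <- rbind(c(0, 0, 1, 1, 1, 0.5),
                rep(2, 6))
  j <- extract_jumps(beta, floor = 1e-6)
  expect_equal(j$sequence, c("seq1", "seq1"))
  expect_equal(j$j, c(3L, 6L))
  expect_equal(j$size, c(1, -0.5))
  # constant row contributes nothing
  expect_false("seq2" %in% j$sequence)
  # sizes equal the row differences wherever above floor
  expect_equal(j$size, diff(beta[1, ])[j$j - 1L])
})

test_that("ruler cutoff follows gamma = max(a sigma, min(D, b sigma))", {
  mk <- function(sizes) tibble::tibble(sequence = "s", j = seq_along(sizes) + 1L,
                                       size = sizes)
  # D = 3 within [a, b]*sigma: gamma = 3, cutoff 0.6
  out <- ruler_threshold(mk(c(3, 0.5, 0.7)), sigma = c(s = 1))
  expect_equal(unique(out$cutoff), 0.6)
  expect_equal(out$size, c(3, 0.7))
  # D = 0.5 below a*sigma: gamma = 1, cutoff 0.2
  out2 <- ruler_threshold(mk(c(0.5, 0.1)), sigma = c(s = 1))
  expect_equal(unique(out2$cutoff), 0.2)
  expect_equal(out2$size, 0.5)
  # D = 7 above b*sigma: gamma = 5, cutoff 1.0
  out3 <- ruler_threshold(mk(c(7, 0.9)), sigma = c(s = 1))
  expect_equal(unique(out3$cutoff), 1.0)
  expect_equal(out3$size, 7)

  expect_error(ruler_threshold(mk(1), sigma = c(s = 0)), "degenerate")

  # scale equivariance: retained set unchanged when everything scales
  set.seed(30)
  sizes <- rnorm(20)
  keep1 <- ruler_threshold(mk(sizes), sigma = c(s = 0.5))$j
  keep2 <- ruler_threshold(mk(sizes * 13), sigma = c(s = 0.5 * 13))$j
  expect_equal(keep1, keep2)
})

test_that("segments partition the grid with means recomputed from the data", {
  set.seed(31)
  y <- rnorm(100)
  sm <- signal_matrix(rbind(y), chrom = "4", positions = 1:100, labels = "s")
  # no jumps: one segment with the observed mean
  seg0 <- jumps_to_segments(tibble::tibble(sequence = character(), j = integer()), sm)
  expect_equal(nrow(seg0), 1L)
  expect_equal(seg0$start, 1L)
  expect_equal(seg0$end, 100L)
  expect_equal(seg0$mean, mean(y))
  # one jump at 51
  seg1 <- jumps_to_segments(tibble::tibble(sequence = "s", j = 51L), sm)
  expect_equal(seg1$start, c(1L, 51L))
  expect_equal(seg1$end, c(50L, 100L))
  expect_equal(seg1$mean, c(mean(y[1:50]), mean(y[51:100])))
  # partition invariant with masked values present (second row keeps the
  # union-grid invariant satisfied)
  ym <- y; ym[c(10:20, 60)] <- NA
  smm <- signal_matrix(rbind(ym, y), chrom = "4", positions = 1:100,
                       labels = c("s", "t"))
  segm <- jumps_to_segments(tibble::tibble(sequence = "s", j = c(15L, 61L)), smm)
  segm <- segm[segm$sequence == "s", ]
  expect_equal(segm$start, c(1L, 15L, 61L))
  expect_equal(segm$end, c(14L, 60L, 100L))
  expect_equal(sum(segm$n_probes), 100L)
  expect_equal(segm$n_obs[1], sum(is.finite(ym[1:14])))
  # a segment with no observations inherits the fitted level and is flagged
  ym2 <- y; ym2[40:60] <- NA
  smm2 <- signal_matrix(rbind(ym2, y), chrom = "4", positions = 1:100,
                        labels = c("s", "t"))
  beta <- rbind(rep(0.7, 100), rep(0, 100))
  seg2 <- jumps_to_segments(tibble::tibble(sequence = "s", j = c(40L, 61L)), smm2,
                            beta = beta)
  seg2 <- seg2[seg2$sequence == "s", ]
  expect_true(seg2$fitted_only[2])
  expect_equal(seg2$mean[2], 0.7)
})

test_that("change points from several signals combine by union", {
  a <- tibble::tibble(sequence = "s", j = c(10L, 30L), size = c(1, -1))
  b <- tibble::tibble(sequence = "t", j = 20L, size = 0.5)
  u <- union_changepoints(list(a, b))
  expect_equal(sort(unique(u$j)), c(10L, 20L, 30L))
  expect_equal(sort(unique(u$sequence)), c("s", "t"))
  # union with itself / with an empty set is the identity on indices
  expect_equal(unique(union_changepoints(list(a, a))$j), c(10L, 30L))
  e <- tibble::tibble(sequence = character(), j = integer(), size = numeric())
  expect_equal(unique(union_changepoints(list(a, e))$j), c(10L, 30L))
})

test_that("mBIC prefers the true change set over augmented ones", {
  set.seed(32)
  y <- c(rnorm(200), rnorm(200, 4))
  # true candidate first (largest size), spurious ones after
  cand <- tibble::tibble(sequence = "s", j = c(201L, 77L, 310L),
                         size = c(4, 0.3, 0.2))
  kept <- mbic_threshold(y, cand)
  expect_equal(kept, 201L)
  # pure noise with weak candidates: nothing retained
  y0 <- rnorm(400)
  kept0 <- mbic_threshold(y0, tibble::tibble(sequence = "s",
                                             j = c(100L, 200L, 300L),
                                             size = c(0.3, 0.2, 0.1)))
  expect_length(kept0, 0L)
})

test_that("two-stage segmentation never adds change points beyond the lax fit", {
  set.seed(33)
  sim <- generate_cohort(2, 400, list(cnv_spec(100, 30, 1, carriers = 1)),
                         noise = noise_spec(lrr_sd = 0.25), seed = 33)
  sigma <- c(0.25, 0.25)
  fit <- fit_gfl(sim$lrr, default_penalties(sigma, 400, 2, p = 0.5))
  cand <- extract_jumps(fit, sigma = sigma)
  segs <- segment_gfl(fit, sigma = sigma)
  kept <- attr(segs, "jumps")
  expect_true(all(paste(kept$sequence, kept$j) %in% paste(cand$sequence, cand$j)))
  # segments partition per sequence
  for (lab in unique(segs$sequence)) {
    s <- segs[segs$sequence == lab, ]
    expect_equal(s$start[1], 1L)
    expect_equal(s$end[nrow(s)], 400L)
    if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)] + 1L)
  }
})
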