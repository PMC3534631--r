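test_that("generators are reproducible and respect the truth bookkeeping", {
  specs <- list(cnv_spec(50, 10, 1, carriers = 1), cnv_spec(120, 20, 3, carriers = 2:3))
  a <- generate_cohort(3, 200, specs, seed = 99)
  b <- generate_cohort(3, 200, specs, seed = 99)
  expect_identical(a$lrr$values, b$lrr$values)
  expect_identical(a$baf$values, b$baf$values)
  # per-SNP truth area = sum of lengths x carriers
  expect_equal(sum(a$truth$cn != 2L), 10 * 1 + 20 * 2)
  # no specs: all-diploid truth, near-zero mean LRR
  n0 <- generate_cohort(2, 500, list(), noise = noise_spec(lrr_sd = 0.2), seed = 1)
  expect_true(all(n0$truth$cn == 2L))
  expect_lt(max(abs(rowMeans(n0$lrr$values))), 3 * 0.2 / sqrt(500))
  # overlapping specs for one carrier are rejected
  expect_error(
    generate_cohort(2, 100, list(cnv_spec(10, 20, 1), cnv_spec(25, 10, 3))),
    "overlapping")
  expect_error(cnv_spec(1, 10, 2), "state 2")
})

test_that("the noiseless limit is exactly piecewise constant and recoverable", {
  model <- state_model()
  sim <- generate_cohort(1, 120, list(cnv_spec(51, 20, 1)),
                         noise = noise_spec(lrr_sd = 1e-9), model = model, seed = 5)
  inside <- sim$lrr$values[1, 51:70]
  outside <- sim$lrr$values[1, -(51:70)]
  expect_equal(inside, rep(model$lrr_mean[2], 20), tolerance = 1e-6)
  expect_equal(outside, rep(0, 100), tolerance = 1e-6)
  # a nearly unpenalized fit plus thresholding recovers the exact boundaries
  fit <- fit_gfl(sim$lrr, penalty_config(lambda2 = 1e-4, epsilon = 1e-16))
  jumps <- extract_jumps(fit, floor = 0.1)
  expect_equal(jumps$j, c(51L, 71L))
})

test_that("tumor dilution mixes LRR and BAF means by the contamination fraction", {
  # pure normal: diploid everywhere
  p1 <- generate_tumor_dilution(list(cnv_spec(11, 20, 1)), alpha = 1, N = 100,
                                noise = noise_spec(lrr_sd = 1e-9,
                                                   baf_sd_het = 1e-9,
                                                   baf_sd_homo = 1e-9,
                                                   outlier_frac = 0),
                                seed = 7)
  expect_equal(max(abs(p1$lrr$values)), 0, tolerance = 1e-6)
  het <- abs(p1$baf$values[1, ] - 0.5) < 0.25
  expect_true(all(abs(p1$baf$values[1, het] - 0.5) < 1e-6))

  # pure tumor hemizygous deletion: LRR mean log2(1/2) = -1
  p0 <- generate_tumor_dilution(list(cnv_spec(11, 20, 1)), alpha = 0, N = 100,
                                noise = noise_spec(lrr_sd = 1e-9,
                                                   baf_sd_het = 1e-9,
                                                   baf_sd_homo = 1e-9,
                                                   outlier_frac = 0),
                                seed = 8)
  expect_equal(unique(round(p0$lrr$values[1, 11:30], 4)), -1)

  # 50/50 one-copy gain: n_eff = 2.5, het BAF centers at 0.4 / 0.6,
  # LRR mean log2(2.5/2)
  p5 <- generate_tumor_dilution(list(cnv_spec(11, 80, 3)), alpha = 0.5, N = 100,
                                noise = noise_spec(lrr_sd = 1e-9,
                                                   baf_sd_het = 1e-9,
                                                   baf_sd_homo = 1e-9,
                                                   outlier_frac = 0),
                                seed = 9)
  expect_equal(unique(round(p5$lrr$values[1, 11:90], 6)), round(log2(2.5 / 2), 6))
  reg <- p5$baf$values[1, 11:90]
  hetv <- reg[reg > 0.05 & reg < 0.95]
  expect_true(all(abs(hetv - 0.4) < 1e-6 | abs(hetv - 0.6) < 1e-6))
  expect_true(length(hetv) > 0)

  # homozygous deletion at alpha = 0 hits the LRR floor, BAF uninformative
  ph <- generate_tumor_dilution(list(cnv_spec(11, 30, 0)), alpha = 0, N = 100,
                                noise = noise_spec(lrr_sd = 1e-9), seed = 10,
                                lrr_floor = -5)
  expect_equal(unique(round(ph$lrr$values[1, 11:40], 4)), -5)

  # CN-LOH: copy number 2, B-allele count 0 or 2 at heterozygous germline
  pl <- generate_tumor_dilution(list(cnv_spec(11, 80, 2, allele = c(2, 0))),
                                alpha = 0, N = 100,
                                noise = noise_spec(lrr_sd = 1e-9,
                                                   baf_sd_het = 1e-9,
                                                   baf_sd_homo = 1e-9,
                                                   outlier_frac = 0),
                                seed = 11)
  expect_equal(max(abs(pl$lrr$values[1, 11:90])), 0, tolerance = 1e-6)
  v <- pl$baf$values[1, 11:90]
  expect_true(all(pmin(abs(v), abs(v - 1)) < 1e-6))
  expect_true(pl$truth$segments$loh[1])

  expect_error(generate_tumor_dilution(list(), alpha = 2), "\\[0, 1\\]")
})

test_that("dilution is continuous in the contamination fraction", {
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    sim <- generate_tumor_dilution(list(cnv_spec(11, 50, 1)), alpha = a, N = 100,
                                   noise = noise_spec(lrr_sd = 1e-9), seed = 3)
    mean(sim$lrr$values[1, 11:60])
  }, numeric(1))
  expect_equal(means, log2((2 * c(0, 0.25, 0.5, 0.75, 1) +
                              (1 - c(0, 0.25, 0.5, 0.75, 1))) / 2),
               tolerance = 1e-4)
  expect_true(all(diff(means) > 0))
})

test_that("pedigree carriers are drawn at the sharing proportion", {
  # p_share = 1: everyone carries everything
  all1 <- generate_pedigree_cohort(5, 60, p_share = 1,
                                   specs = list(cnv_spec(11, 10, 1)), seed = 12)
  expect_true(all(all1$truth$cn[, 11:20] == 1L))
  # tiny p_share: at least one carrier is forced
  low <- generate_pedigree_cohort(5, 60, p_share = 1e-6,
                                  specs = list(cnv_spec(11, 10, 1)), seed = 13)
  expect_gte(sum(low$truth$cn[, 11] == 1L), 1L)
  # realized carrier fraction matches p_share within Monte Carlo error
  set.seed(14)
  M <- 12; p <- 0.4; reps <- 300
  frac <- vapply(seq_len(reps), function(r) {
    sim <- generate_pedigree_cohort(M, 10, p_share = p,
                                    specs = list(cnv_spec(2, 3, 1)),
                                    noise = noise_spec(lrr_sd = 0.5))
    mean(sim$truth$cn[, 2] == 1L)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (M * reps))
  # the forced minimum carrier inflates the mean slightly; allow for it
  expect_lt(abs(mean(frac) - p), 3 * se + 1 / M * (1 - p)^M + 0.02)
})

test_that("per-SNP scoring matches hand-computed confusion counts", {
  specs <- list(cnv_spec(11, 20, 1, carriers = 1), cnv_spec(61, 10, 3, carriers = 2))
  sim <- generate_cohort(2, 100, specs, seed = 20)
  perfect <- tibble::tibble(
    sequence = c("sample01", "sample02"), start = c(11L, 61L), end = c(30L, 70L),
    state = c(1L, 3L), accepted = TRUE)
  sc <- score_detection(sim$truth, perfect)
  expect_equal(sc$tpr[sc$type == "overall" & sc$size == "all"], 1)
  expect_equal(sc$fdr[sc$type == "overall" & sc$size == "all"], 0)

  none <- perfect[0, ]
  sc0 <- score_detection(sim$truth, none)
  expect_equal(sc0$tpr[sc0$type == "overall" & sc0$size == "all"], 0)
  expect_equal(sc0$fdr[sc0$type == "overall" & sc0$size == "all"], 0)
  expect_true(sc0$no_calls[sc0$type == "overall" & sc0$size == "all"])

  # random calls on ~10% of probes against 10% true variants: FDR near 90%
  set.seed(21)
  specs2 <- list(cnv_spec(1, 100, 1, carriers = 1))
  sim2 <- generate_cohort(1, 1000, specs2, seed = 21)
  rand_starts <- sample(seq(1L, 991L, by = 10L), 10)
  rand <- tibble::tibble(sequence = "sample01", start = rand_starts,
                         end = rand_starts + 9L, state = 1L, accepted = TRUE)
  sc2 <- score_detection(sim2$truth, rand)
  expect_equal(sc2$fdr[sc2$type == "overall" & sc2$size == "all"], 0.9,
               tolerance = 0.35)
})
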