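test_that("rescaled range matches the hand-worked example and scales out", {
  rs <- rescaled_range(c(1, -1, 1, -1))
  expect_equal(rs$R, 1)
  expect_equal(rs$S, 1)
  expect_error(rescaled_range(rep(3, 10)), "degenerate")
  set.seed(1)
  x <- rnorm(64)
  a <- rescaled_range(x)
  b <- rescaled_range(7.3 * x)
  expect_equal(a$R / a$S, b$R / b$S, tolerance = 1e-12)
})

test_that("single-scale Hurst formula reproduces its degenerate example", {
  h <- hurst_printed(c(1, -1, 1, -1))
  expect_equal(h$H, 0)
  expect_identical(h$method, "printed_single_scale")
  # white noise: biased single-scale value, bracketed by simulation
  set.seed(8)
  hs <- replicate(200, hurst_printed(rnorm(1280))$H)
  expect_gt(mean(hs), 0.45)
  expect_lt(mean(hs), 0.60)
  x <- rnorm(500)
  expect_identical(hurst_printed(x)$H, hurst_printed(x)$H)
})

test_that("R/S regression uses correct per-scale statistics", {
  set.seed(40)
  for (r in 1:5) {
    x <- rnorm(1280) * 10 + 5
    h <- hurst_rs(x)
    expect_equal(h$rs_values, rs_scales_loop(x), tolerance = 1e-10)
    expect_identical(h$scales, 8 * 2^(0:6))
  }
  expect_error(hurst_rs(rnorm(20)), "fewer than 3")
})

test_that("trended series saturate the R/S estimator", {
  expect_gt(hurst_rs(as.numeric(1:1280))$H, 0.9)
})

test_that("ordinal motifs index permutations with stable ties", {
  expect_identical(ordinal_motif(c(1, 2, 3)), 0L)
  idx <- apply(rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                     c(3,1,2), c(3,2,1)), 1, ordinal_motif)
  expect_identical(sort(idx), 0:5)
  expect_identical(ordinal_motif(c(2, 2, 1)), ordinal_motif(c(2, 3, 1)))
  expect_identical(ordinal_motif(c(5, 5, 5, 5)),
                   ordinal_motif(c(1, 2, 3, 4)))
})

test_that("AAPE reproduces the hand-worked d = 2 example", {
  # x = (1,3,2): w(1,3) = 0.25*4 + 0.5*2 = 2, w(3,2) = 0.25*5 + 0.5*1 = 1.75;
  # p = (8/15, 7/15) -> 0.690923 nats
  expect_equal(aape(c(1, 3, 2), d = 2, l = 1, A = 0.5),
               -(8 / 15) * log(8 / 15) - (7 / 15) * log(7 / 15),
               tolerance = 1e-12)
  expect_equal(aape(c(1, 3, 2), d = 2), aape_brute(c(1, 3, 2), 2, 1, 0.5),
               tolerance = 1e-12)
})

test_that("AAPE equals the brute-force accumulator across parameters", {
  set.seed(33)
  for (r in 1:10) {
    x <- switch(sample(3, 1),
                rnorm(sample(20:64, 1)),
                cumsum(rnorm(sample(20:64, 1))),
                round(rnorm(sample(20:64, 1)), 1))  # ties present
    for (d in 2:4) for (l in 1:2) for (A in c(0, 0.5, 1)) {
      if (length(x) <= d * l) next
      expect_equal(aape(x, d = d, l = l, A = A), aape_brute(x, d, l, A),
                   tolerance = 1e-12)
    }
  }
})

test_that("AAPE respects its bounds and degenerate cases", {
  set.seed(17)
  for (r in 1:200) {
    d <- sample(2:4, 1)
    x <- rnorm(sample(30:100, 1))
    a <- aape(x, d = d)
    expect_gte(a, 0)
    expect_lte(a, log(factorial(d)) + 1e-12)
  }
  expect_equal(aape(1:50, d = 3), 0)              # single motif
  expect_equal(aape(exp(seq(0, 3, length.out = 40)), d = 4), 0)
  expect_error(aape(rep(2, 50), d = 3), "degenerate")
})

test_that("amplitude scaling moves AAPE but not classical PE", {
  # high-amplitude segment strictly above the rest: doubling it preserves
  # every within-window ordering (PE fixed) but shifts the weight balance
  set.seed(2)
  lo <- runif(60, 0, 1)
  hi <- runif(60, 10, 20)
  x1 <- c(lo, hi, lo)
  x2 <- c(lo, 2 * hi, lo)
  cfg <- aape_config(d = 3)
  expect_equal(perm_entropy(x1, cfg), pe_brute(x1, 3, 1), tolerance = 1e-12)
  expect_identical(perm_entropy(x1, cfg), perm_entropy(x2, cfg))
  expect_gt(abs(aape(x1, cfg) - aape(x2, cfg)), 1e-4)
})

test_that("A = 1 and A = 0 reduce to pure amplitude / difference weighting", {
  set.seed(9)
  x <- rnorm(80)
  expect_equal(aape(x, d = 3, A = 1), aape_brute(x, 3, 1, 1),
               tolerance = 1e-12)
  expect_equal(aape(x, d = 3, A = 0), aape_brute(x, 3, 1, 0),
               tolerance = 1e-12)
  # zero-amplitude alternating series: A = 1 weights all motifs equally by
  # |x|, A = 0 by successive jumps; both still defined and bounded
  alt <- rep(c(-1, 1), 30)
  expect_lte(aape(alt, d = 2, A = 0), log(2))
})

test_that("feature fusion concatenates named families and guards misuse", {
  hur <- setNames(runif(3), paste0("Hur_", c("AF3", "F7", "F3")))
  aap <- setNames(runif(3), paste0("AAPE_", c("AF3", "F7", "F3")))
  fused <- compen_fuse(hur, aap)
  expect_length(fused, 6)
  expect_identical(names(fused), c(names(hur), names(aap)))
  expect_identical(compen_fuse(numeric(0), aap), aap)
  expect_error(compen_fuse(hur, setNames(runif(3), names(hur))), "collision")
})

test_that("feature table has the protocol geometry and column layout", {
  cfg <- make_tiny_cohort(seed = 12, n_channels = 2)
  segs <- do.call(c, lapply(generate_cohort(cfg), segment_recording))
  ft <- build_feature_table(segs, layout = "COMPEN")
  expect_identical(nrow(ft$matrix), 30L)            # 10 subjects x 3 trials
  expect_identical(sum(ft$labels == "female"), 12L) # 4 F x 3 trials
  expect_identical(sum(ft$labels == "male"), 18L)
  expect_identical(ncol(ft$matrix), 16L)            # 2 ch x 4 emo x 2 kinds
  hur <- build_feature_table(segs, layout = "HUR")
  expect_identical(ncol(hur$matrix), 8L)
  expect_true(all(startsWith(colnames(hur$matrix), "Hur_")))
  # channel-major, emotion-minor, alphabetical
  expect_identical(colnames(hur$matrix)[1:4],
                   paste0("Hur_AF3_", sort(DEFAULT_EMOTIONS)))
})

test_that("feature table is invariant to segment order and flags gaps", {
  cfg <- make_tiny_cohort(seed = 13, n_channels = 2, n_female = 1,
                          n_male = 1)
  segs <- do.call(c, lapply(generate_cohort(cfg), segment_recording))
  ft1 <- build_feature_table(segs, layout = "HUR")
  set.seed(99)
  ft2 <- build_feature_table(sample(segs), layout = "HUR")
  expect_identical(ft1$matrix, ft2$matrix)
  expect_identical(ft1$labels, ft2$labels)
  expect_error(build_feature_table(segs[-1], layout = "HUR"),
               "missing segment cells")
})

test_that("per-emotion instance layout is available", {
  cfg <- make_tiny_cohort(seed = 14, n_channels = 2, n_female = 1,
                          n_male = 1)
  segs <- do.call(c, lapply(generate_cohort(cfg), segment_recording))
  ft <- build_feature_table(segs, layout = "COMPEN",
                            instance_unit = "subject_trial_emotion")
  expect_identical(nrow(ft$matrix), 24L)  # 2 subj x 3 trials x 4 emotions
  expect_identical(ncol(ft$matrix), 4L)   # 2 channels x 2 kinds
})

test_that("with 14 channels the layouts have 56 and 112 columns", {
  cfg <- make_tiny_cohort(seed = 15, n_channels = 14, duration_s = 10,
                          n_female = 1, n_male = 1)
  segs <- do.call(c, lapply(generate_cohort(cfg),
                            segment_recording, n_trials = 1))
  expect_identical(ncol(build_feature_table(segs, layout = "HUR")$matrix),
                   56L)
  expect_identical(ncol(build_feature_table(segs, layout = "COMPEN")$matrix),
                   112L)
})
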