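test_that("fGn with H = 0.5 is white noise and generation is deterministic", {
  x <- generate_fgn(1e4, 0.5, seed = 42)
  r1 <- acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 3 / sqrt(1e4))
  expect_identical(x, generate_fgn(1e4, 0.5, seed = 42))
  expect_false(identical(x, generate_fgn(1e4, 0.5, seed = 43)))
})

test_that("fGn empirical autocovariance matches the closed form", {
  # gamma(k)/gamma(0) = ((k+1)^2H - 2 k^2H + (k-1)^2H) / 2
  H <- 0.8
  gamma_cf <- function(k) ((k + 1)^(2 * H) - 2 * k^(2 * H) +
                             abs(k - 1)^(2 * H)) / 2
  n <- 2^14
  reps <- 200
  # known-zero-mean autocovariance: demeaning would bias long-memory
  # series by O(n^{2H-2}), which at H = 0.8 is not negligible
  acfs <- vapply(seq_len(reps), function(r) {
    x <- generate_fgn(n, H, seed = 1000 + r)
    vapply(1:5, function(k) mean(x[1:(n - k)] * x[(k + 1):n]), numeric(1))
  }, numeric(5))
  m <- rowMeans(acfs)
  se <- apply(acfs, 1, sd) / sqrt(reps)
  for (k in 1:5) {
    expect_lt(abs(m[k] - gamma_cf(k)), 3 * se[k] + 0.005)
  }
  expect_lt(abs(m[1] - (2^(2 * H - 1) - 1)), 0.02)
})

test_that("fGn rejects invalid parameters", {
  expect_error(generate_fgn(1, 0.5), "n")
  expect_error(generate_fgn(100, 0), "hurst")
  expect_error(generate_fgn(100, 1), "hurst")
  expect_error(generate_fgn(100, 0.5, sigma = 0), "sigma")
})

test_that("MIX process orders AAPE by irregularity", {
  # endpoints: periodic < random, every seed
  for (s in 1:5) {
    a0 <- aape(generate_mix(1280, 0, seed = s), d = 4)
    a1 <- aape(generate_mix(1280, 1, seed = s), d = 4)
    expect_lt(a0, a1)
  }
  # mean AAPE strictly increases over the lower grid; the p = 0.75 -> 1 step
  # genuinely reverses by a hair (amplitude-weighted motifs of the mixture
  # spread slightly wider than pure noise), so the endpoint ordering is the
  # asserted upper comparison
  grid <- c(0, 0.25, 0.5, 0.75)
  means <- vapply(grid, function(p)
    mean(vapply(1:50, function(s)
      aape(generate_mix(1280, p, seed = 100 * s), d = 4), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) > 0))
  m1 <- mean(vapply(1:50, function(s)
    aape(generate_mix(1280, 1, seed = 100 * s), d = 4), numeric(1)))
  expect_gt(m1, means[1])
  expect_identical(generate_mix(500, 0.3, seed = 9),
                   generate_mix(500, 0.3, seed = 9))
})

test_that("artifact injection adds line power and leaves input untouched", {
  cfg <- make_tiny_cohort(seed = 3, n_channels = 1)
  rec <- generate_cohort(cfg)[[1]]
  none <- inject_artifacts(rec, list(line_amp = 0, drift_amp = 0,
                                     burst_rate = 0), seed = 1)
  expect_identical(none$data, rec$data)

  lined <- inject_artifacts(rec, list(line_amp = 1, drift_amp = 0,
                                      burst_rate = 0), seed = 1)
  psd50 <- function(x) {
    sp <- Mod(fft(x))^2
    f <- rec$fs * (seq_along(x) - 1) / length(x)
    sum(sp[abs(f - 50) < 0.2])
  }
  expect_gt(psd50(lined$data[1, ]), psd50(rec$data[1, ]))
  expect_identical(rec$data, generate_cohort(cfg)[[1]]$data)  # input unmodified
})

test_that("burst count is Poisson with the configured rate", {
  rec <- recording("S1", "female", "anger",
                   matrix(sin(2 * pi * 10 * seq_len(3840) / 128), 1),
                   128, "AF3")
  count_bursts <- function(s) {
    out <- inject_artifacts(rec, list(line_amp = 0, drift_amp = 0,
                                      burst_rate = 2), seed = s)
    resid <- abs(out$data[1, ] - rec$data[1, ])
    # bursts are 0.5 s events of oscillating noise: merge suprathreshold
    # samples closer than 0.5 s into one event before counting
    idx <- which(resid > 1e-9)
    if (length(idx) == 0) return(0)
    sum(diff(idx) > 64) + 1
  }
  counts <- vapply(1:500, count_bursts, numeric(1))
  expect_lt(abs(mean(counts) - 1), 0.15)
})

test_that("cohort geometry, labels, and determinism are exact", {
  cfg <- make_tiny_cohort(seed = 7)
  recs <- generate_cohort(cfg)
  expect_length(recs, 40)     # (4 + 6) subjects x 4 emotions
  genders <- vapply(recs, `[[`, "", "gender")
  expect_identical(sum(genders == "female"), 16L)

  all_male <- generate_cohort(make_tiny_cohort(seed = 7, n_female = 0))
  expect_true(all(vapply(all_male, `[[`, "", "gender") == "male"))

  again <- generate_cohort(cfg)
  for (i in seq_along(recs)) expect_identical(recs[[i]]$data, again[[i]]$data)
})

test_that("adding subjects does not perturb existing recordings", {
  small <- generate_cohort(make_tiny_cohort(seed = 5, n_male = 5))
  big <- generate_cohort(make_tiny_cohort(seed = 5, n_male = 6))
  ids <- function(l) vapply(l, function(r) paste(r$subject_id, r$emotion), "")
  common <- intersect(ids(small), ids(big))
  expect_length(common, 36)   # 9 subjects x 4 emotions
  for (key in common) {
    a <- small[[match(key, ids(small))]]
    b <- big[[match(key, ids(big))]]
    expect_identical(a$data, b$data)
  }
})

test_that("downstream Hurst estimates separate groups with distinct H", {
  cfg <- make_tiny_cohort(seed = 11, n_channels = 4,
                          hurst_by_group = list(female = 0.6, male = 0.75),
                          mix_p_by_group = list(female = 0.35, male = 0.35))
  segs <- do.call(c, lapply(generate_cohort(cfg), segment_recording))
  lf <- feature_long(segs)
  subj <- aggregate(value_hur ~ subject + gender, lf, mean)
  tt <- t.test(value_hur ~ gender, subj)
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(subj$value_hur[subj$gender == "female"]),
            mean(subj$value_hur[subj$gender == "male"]))
})

test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(emotions = c("a", "b", "c")), "4 distinct")
  expect_error(cohort_config(emotions = c("a", "a", "b", "c")), "4 distinct")
  expect_error(cohort_config(hurst_by_group = list(female = 1.2, male = 0.7)),
               "hurst_by_group")
  expect_error(cohort_config(mix_p_by_group = list(female = -0.1, male = 0.5)),
               "mix_p_by_group")
  expect_error(cohort_config(duration_s = 10.41), "integer sample count")
})

test_that("recording CSV round trip is lossless and errors are informative", {
  cfg <- make_tiny_cohort(seed = 2, n_channels = 3, duration_s = 2)
  rec <- generate_cohort(cfg)[[1]]
  path <- file.path(tempdir(), "rec_roundtrip.csv")
  write_recording(rec, path)
  back <- read_recording(path, "csv")
  expect_lt(max(abs(back$data - rec$data)), 1e-9)
  expect_identical(back$gender, rec$gender)
  expect_identical(back$channel_labels, rec$channel_labels)

  df <- read.csv(path, check.names = FALSE)
  df[[rec$channel_labels[2]]] <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path, "csv"), rec$channel_labels[2])
  unlink(c(path, paste0(path, ".json")))
})
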