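# Synthetic EEG cohort generator. The study's recordings are not deposited,
# so every downstream stage is exercised on signals whose ground truth is
# known: fractional Gaussian noise with an exact Hurst parameter, MIX(p)
# processes with a known irregularity ordering, and injected line/drift/burst
# artifacts for the denoising stage to remove.

#' Channel labels of the emulated 14-channel headset (10-20 placement)
#' @export
EMOTIV_LABELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                   "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

#' The four emotion conditions of the emulated protocol
#' @export
DEFAULT_EMOTIONS <- c("anger", "happiness", "sadness", "neutral")

#' Cohort configuration for the synthetic EEG generator
#'
#' Describes the geometry of the emulated acquisition protocol (a 14-channel
#' 128 Hz consumer headset, 30 s per emotion block, four emotions, two gender
#' groups) and the statistical structure of each group: the target Hurst
#' exponent per group x emotion, the MIX irregularity parameter p per group x
#' emotion, and artifact levels.
#'
#' Defaults encode the study conditions being emulated: 4 females and
#' 6 males; females have lower long-range dependence than males (H 0.62 vs
#' 0.70, on top of small per-emotion offsets), and the irregularity parameter
#' differs by emotion in opposite directions for the two groups (females more
#' irregular in anger/neutral, less in happiness/sadness). Effect sizes are
#' design parameters of the generator, not estimates of any real population.
#'
#' @param n_female,n_male Subject counts per group.
#' @param emotions Character vector of exactly 4 distinct emotion labels.
#' @param channel_labels Channel montage labels (defaults to the 14 Emotiv
#'   EPOC labels).
#' @param fs Sampling rate in Hz.
#' @param duration_s Seconds per subject x emotion block; `duration_s * fs`
#'   must be a whole number of samples.
#' @param hurst_by_group Named list (`female`, `male`) of per-emotion target
#'   Hurst exponents in (0, 1); scalars are recycled across emotions.
#' @param mix_p_by_group Named list (`female`, `male`) of per-emotion MIX
#'   irregularity parameters in \[0, 1\]; scalars recycled.
#' @param hurst_subject_sd SD of the Gaussian per-subject offset on H
#'   (truncated so each subject's H stays in (0.05, 0.95)).
#' @param mix_weight Weight q of the standardized MIX component in the blend
#'   `(1 - q) * fGn + q * MIX`, in \[0, 1).
#' @param amplitude_uV Per-channel signal scale in microvolts (SD of the
#'   clean signal).
#' @param artifact_params List with `line_amp`, `drift_amp` (amplitudes in
#'   multiples of the clean signal SD) and `burst_rate` (bursts per minute).
#' @param seed Integer seed governing the whole cohort.
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_female = 4L,
                          n_male = 6L,
                          emotions = DEFAULT_EMOTIONS,
                          channel_labels = EMOTIV_LABELS,
                          fs = 128,
                          duration_s = 30,
                          hurst_by_group = list(
                            female = c(anger = 0.64, happiness = 0.63,
                                       sadness = 0.60, neutral = 0.62),
                            male = c(anger = 0.72, happiness = 0.71,
                                     sadness = 0.68, neutral = 0.70)
                          ),
                          mix_p_by_group = list(
                            female = c(anger = 0.45, happiness = 0.25,
                                       sadness = 0.25, neutral = 0.45),
                            male = c(anger = 0.35, happiness = 0.35,
                                     sadness = 0.35, neutral = 0.35)
                          ),
                          hurst_subject_sd = 0.02,
                          mix_weight = 0.35,
                          amplitude_uV = 20,
                          artifact_params = list(line_amp = 1.0,
                                                 drift_amp = 1.0,
                                                 burst_rate = 2),
                          seed = 1L) {
  emotions <- as.character(emotions)
  if (length(emotions) != 4L || anyDuplicated(emotions))
    stop_compen("'emotions' must be exactly 4 distinct labels")
  if (fs <= 0) stop_compen("'fs' must be positive")
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop_compen("'duration_s * fs' must be an integer sample count")
  expand <- function(v, what, lo, hi, open) {
    if (length(v) == 1L) v <- rep(v, 4L)
    if (is.null(names(v)) || !all(emotions %in% names(v))) names(v) <- emotions
    v <- v[emotions]
    bad <- if (open) v <= lo | v >= hi else v < lo | v > hi
    if (any(!is.finite(v)) || any(bad))
      stop_compen(sprintf("'%s' values must lie in %s%g, %g%s", what,
                          if (open) "(" else "[", lo, hi,
                          if (open) ")" else "]"))
    v
  }
  hurst_by_group <- list(
    female = expand(hurst_by_group$female, "hurst_by_group", 0, 1, TRUE),
    male = expand(hurst_by_group$male, "hurst_by_group", 0, 1, TRUE))
  mix_p_by_group <- list(
    female = expand(mix_p_by_group$female, "mix_p_by_group", 0, 1, FALSE),
    male = expand(mix_p_by_group$male, "mix_p_by_group", 0, 1, FALSE))
  if (mix_weight < 0 || mix_weight >= 1)
    stop_compen("'mix_weight' must be in [0, 1)")
  for (p in c("line_amp", "drift_amp", "burst_rate"))
    if (is.null(artifact_params[[p]]) || artifact_params[[p]] < 0)
      stop_compen("artifact_params$", p, " must be a non-negative number")
  structure(list(
    n_female = as.integer(n_female), n_male = as.integer(n_male),
    emotions = emotions, channel_labels = as.character(channel_labels),
    n_channels = length(channel_labels), fs = fs, duration_s = duration_s,
    n_samples = as.integer(round(n_samp)),
    hurst_by_group = hurst_by_group, mix_p_by_group = mix_p_by_group,
    hurst_subject_sd = hurst_subject_sd, mix_weight = mix_weight,
    amplitude_uV = amplitude_uV, artifact_params = artifact_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Construct a single-subject, single-emotion recording
#'
#' @param subject_id Subject identifier.
#' @param gender `"female"` or `"male"`.
#' @param emotion Emotion label.
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel labels, one per row of `data`.
#' @return A list of class `recording`.
#' @export
recording <- function(subject_id, gender, emotion, data, fs, channel_labels) {
  gender <- match.arg(gender, c("female", "male"))
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop_compen("'data' must have one row per channel label (",
                nrow(data), " rows vs ", length(channel_labels), " labels)")
  if (!all(is.finite(data)))
    stop_compen("recording contains non-finite samples")
  rownames(data) <- channel_labels
  structure(list(subject_id = subject_id, gender = gender, emotion = emotion,
                 data = data, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s), emotion %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$gender, x$emotion,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Simulate fractional Gaussian noise by circulant embedding
#'
#' Exact synthesis of stationary Gaussian noise with autocovariance
#' `gamma(k) = sigma^2/2 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})`, the
#' increment process of fractional Brownian motion. The covariance is
#' embedded in a circulant matrix diagonalized by the FFT, so the
#' finite-sample covariance is correct (not an approximation); `H = 0.5`
#' reduces to white Gaussian noise.
#'
#' @param n Number of samples (>= 2).
#' @param hurst Hurst exponent in (0, 1).
#' @param sigma Marginal standard deviation.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of length `n`.
#' @export
generate_fgn <- function(n, hurst, sigma = 1, seed = NULL) {
  if (n < 2) stop_compen("'n' must be >= 2")
  if (hurst <= 0 || hurst >= 1) stop_compen("'hurst' must be in (0, 1)")
  if (sigma <= 0) stop_compen("'sigma' must be positive")
  n <- as.integer(n)
  k <- 0:n
  g <- sigma^2 / 2 *
    (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) + abs(k - 1)^(2 * hurst))
  m <- 2L * n
  circ <- c(g[1:(n + 1L)], g[n:2])
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop_compen("circulant embedding is not positive semi-definite ",
                "(most negative eigenvalue ", format(min(lam)), ")")
  lam[lam < 0] <- 0
  with_seed(seed, {
    # E[z zH] = 2 I and E[z zT] = 0, so Re(F sqrt(lam/m) z) has covariance
    # exactly the embedded circulant (the real part halves it)
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    Re(fft(sqrt(lam / m) * z))[1:n]
  })
}

#' Simulate a MIX(p) irregularity benchmark process
#'
#' Each sample is uniform noise on `[-sqrt(3), sqrt(3)]` with probability
#' `p`, otherwise a fixed-frequency unit-variance sinusoid sample
#' (`sqrt(2) * sin(2*pi*i/period)`). `p = 0` is purely periodic, `p = 1`
#' purely random; entropy measures order the process by `p`, which makes it
#' the standard test signal for irregularity estimators.
#'
#' @param n Number of samples.
#' @param p Irregularity probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @param period Sinusoid period in samples.
#' @return Numeric vector of length `n`.
#' @export
generate_mix <- function(n, p, seed = NULL, period = 12) {
  if (p < 0 || p > 1) stop_compen("'p' must be in [0, 1]")
  det <- sqrt(2) * sin(2 * pi * seq_len(n) / period)
  with_seed(seed, {
    z <- runif(n) < p
    u <- runif(n, -sqrt(3), sqrt(3))
    ifelse(z, u, det)
  })
}

#' Inject line, drift and burst artifacts into a recording
#'
#' Adds, per channel: a 50 Hz sinusoid with random phase (power-line
#' interference), a random-walk baseline drift (power concentrated well below
#' 0.5 Hz), and Poisson-timed transient bursts (0.5 s Hanning-windowed
#' 20--40 Hz noise at `burst_amp` times the channel SD). Amplitudes are
#' expressed in multiples of the clean channel SD. The input recording is not
#' modified.
#'
#' @param rec A [recording()].
#' @param artifact_params List with `line_amp`, `drift_amp`, `burst_rate`
#'   (per minute) and optionally `burst_amp` (default 5).
#' @param seed Integer seed.
#' @return A new `recording` with artifacts added.
#' @export
inject_artifacts <- function(rec, artifact_params, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  line_amp <- artifact_params$line_amp %||% 0
  drift_amp <- artifact_params$drift_amp %||% 0
  burst_rate <- artifact_params$burst_rate %||% 0
  burst_amp <- artifact_params$burst_amp %||% 5
  n <- ncol(rec$data)
  fs <- rec$fs
  tt <- seq_len(n) / fs
  data <- rec$data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    s <- sd(x)
    if (s == 0) s <- 1
    add <- numeric(n)
    ch_seed <- if (is.null(seed)) NULL else derive_seed(seed, ch)
    add <- add + with_seed(ch_seed, {
      out <- numeric(n)
      if (line_amp > 0) {
        phase <- runif(1, 0, 2 * pi)
        out <- out + line_amp * s * sqrt(2) * sin(2 * pi * 50 * tt + phase)
      }
      if (drift_amp > 0) {
        # random-walk drift, band-limited strictly below 0.5 Hz so the
        # conventional highpass can remove it
        w <- cumsum(rnorm(n))
        f <- fs * (0:(n - 1)) / n
        f <- pmin(f, fs - f)
        w <- Re(fft(fft(w) * (f < 0.4), inverse = TRUE)) / n
        w <- w - mean(w)
        sw <- sd(w)
        if (sw > 0) out <- out + drift_amp * s * w / sw
      }
      if (burst_rate > 0) {
        n_burst <- rpois(1, burst_rate * n / fs / 60)
        len <- max(2L, as.integer(round(0.5 * fs)))
        win <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
        for (b in seq_len(n_burst)) {
          onset <- sample.int(max(1L, n - len + 1L), 1L)
          noise <- rnorm(len)
          # crude 20-40 Hz shaping: difference of smoothed noise via FFT mask
          noise <- .band_noise(len, fs, 20, 40, noise)
          sn <- sd(noise)
          if (sn > 0) {
            seg <- onset:(onset + len - 1L)
            out[seg] <- out[seg] + burst_amp * s * win * noise / sn
          }
        }
      }
      out
    })
    data[ch, ] <- x + add
  }
  recording(rec$subject_id, rec$gender, rec$emotion, data, fs,
            rec$channel_labels)
}

# FFT brick-wall bandpass of a white-noise vector; used only to shape burst
# artifacts, where exact filter rolloff is irrelevant.
.band_noise <- function(n, fs, lo, hi, noise) {
  f <- fs * (0:(n - 1)) / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= lo & f <= hi)
  Re(fft(fft(noise) * mask, inverse = TRUE)) / n
}

#' Generate a synthetic EEG cohort
#'
#' One recording per subject x emotion. Each channel is the blend
#' `amplitude_uV * ((1 - q) * fGn(H) + q * MIX(p))` where H is the group x
#' emotion target plus a truncated-Gaussian per-subject offset, p is the
#' group x emotion irregularity parameter and q = `mix_weight`; artifacts are
#' then injected per [inject_artifacts()]. All randomness derives from
#' `config$seed` through per-subject/emotion/channel sub-streams, so the
#' cohort is bit-reproducible and adding subjects does not perturb existing
#' ones.
#'
#' @param config A [cohort_config()].
#' @return List of [recording()] objects, length
#'   `(n_female + n_male) * length(emotions)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- data.frame(
    subject_id = c(sprintf("F%02d", seq_len(config$n_female)),
                   sprintf("M%02d", seq_len(config$n_male))),
    gender = rep(c("female", "male"), c(config$n_female, config$n_male)),
    stringsAsFactors = FALSE)
  n <- config$n_samples
  q <- config$mix_weight
  out <- vector("list", nrow(subjects) * length(config$emotions))
  idx <- 0L
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    # per-subject H offset, truncated so H stays inside (0.05, 0.95)
    h_off <- with_seed(derive_seed(config$seed, si, 0L, 0L),
                       rnorm(1, 0, config$hurst_subject_sd))
    for (ei in seq_along(config$emotions)) {
      emo <- config$emotions[ei]
      h_target <- config$hurst_by_group[[subj$gender]][[emo]] + h_off
      h_target <- min(max(h_target, 0.05), 0.95)
      p_mix <- config$mix_p_by_group[[subj$gender]][[emo]]
      data <- matrix(0, config$n_channels, n)
      for (ci in seq_len(config$n_channels)) {
        sd_ch <- derive_seed(config$seed, si, ei, ci)
        base <- generate_fgn(n, h_target, 1, seed = sd_ch)
        mixs <- generate_mix(n, p_mix, seed = derive_seed(sd_ch, 7L))
        mixs <- (mixs - mean(mixs)) / max(sd(mixs), .Machine$double.eps)
        data[ci, ] <- config$amplitude_uV * ((1 - q) * base + q * mixs)
      }
      rec <- recording(subj$subject_id, subj$gender, emo, data, config$fs,
                       config$channel_labels)
      rec <- inject_artifacts(rec, config$artifact_params,
                              seed = derive_seed(config$seed, si, ei, 999L))
      idx <- idx + 1L
      out[[idx]] <- rec
    }
  }
  out
}

#' Generate a cohort with group information split across channel halves
#'
#' Constructs the "split information" experiment: the first half of the
#' channels differ between genders in long-range dependence only (Hurst
#' exponents `hurst_pair`, identical irregularity), the second half in
#' irregularity only (MIX parameters `mix_p_pair`, identical H). Neither
#' feature family alone sees the whole group signal, so fusing complexity
#' and irregularity features should not lose accuracy relative to either
#' family — the structural point of the fused feature set.
#'
#' @param n_female,n_male Subject counts.
#' @param n_channels Total channels (even); half carry each contrast.
#' @param hurst_pair `c(female, male)` H on the complexity channels.
#' @param hurst_common H on the irregularity channels (both genders).
#' @param mix_p_pair `c(female, male)` MIX p on the irregularity channels.
#' @param mix_p_common MIX p on the complexity channels (both genders).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [cohort_config()] (e.g.
#'   `artifact_params`, `mix_weight`).
#' @return List of [recording()]s with `n_channels` channels each.
#' @export
generate_split_cohort <- function(n_female = 4L, n_male = 6L,
                                  n_channels = 14L,
                                  hurst_pair = c(0.64, 0.68),
                                  hurst_common = 0.66,
                                  mix_p_pair = c(0.28, 0.48),
                                  mix_p_common = 0.38,
                                  seed = 1L, ...) {
  n_half <- n_channels %/% 2L
  labels <- EMOTIV_LABELS[seq_len(2L * n_half)]
  base <- list(n_female = n_female, n_male = n_male,
               channel_labels = labels[seq_len(n_half)], seed = seed, ...)
  cfg_h <- do.call(cohort_config, c(base, list(
    hurst_by_group = list(female = hurst_pair[1], male = hurst_pair[2]),
    mix_p_by_group = list(female = mix_p_common, male = mix_p_common))))
  base$channel_labels <- labels[(n_half + 1L):(2L * n_half)]
  base$seed <- derive_seed(seed, 2L)
  cfg_p <- do.call(cohort_config, c(base, list(
    hurst_by_group = list(female = hurst_common, male = hurst_common),
    mix_p_by_group = list(female = mix_p_pair[1], male = mix_p_pair[2]))))
  ch <- generate_cohort(cfg_h)
  cp <- generate_cohort(cfg_p)
  mapply(function(a, b) {
    stopifnot(a$subject_id == b$subject_id, a$emotion == b$emotion)
    recording(a$subject_id, a$gender, a$emotion, rbind(a$data, b$data),
              a$fs, c(a$channel_labels, b$channel_labels))
  }, ch, cp, SIMPLIFY = FALSE)
}

#' Write a recording as CSV plus a JSON sidecar manifest
#'
#' First column is time in seconds, then one column per channel label. The
#' sidecar (`<path>.json`) records subject, gender, emotion, sampling rate.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- data.frame(time = seq_len(ncol(rec$data)) / rec$fs,
                   t(rec$data), check.names = FALSE)
  names(df) <- c("time", rec$channel_labels)
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, gender = rec$gender,
               emotion = rec$emotion, fs = rec$fs,
               channel_labels = rec$channel_labels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
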