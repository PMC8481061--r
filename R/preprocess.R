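# Denoising composition (notch -> band limiting -> wavelet shrinkage) and
# trial segmentation.

#' Denoise one EEG channel
#'
#' Applies, in order: 50 Hz notch, Butterworth band limiting (both
#' zero-phase), then level-4 Symlet-9 wavelet decomposition with per-level
#' SURE soft thresholding of the detail bands (the approximation band is
#' untouched) and reconstruction. Output length equals input length. Pass
#' `filter_spec = NULL` to bypass the conventional filters (used by tests to
#' isolate the wavelet stage).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param filter_spec A [filter_spec()] or `NULL`.
#' @param wavelet_config A [wavelet_config()].
#' @return Denoised series with attribute `thresholds`.
#' @export
denoise <- function(x, fs, filter_spec = compen::filter_spec(),
                    wavelet_config = compen::wavelet_config()) {
  y <- as.numeric(x)
  if (!is.null(filter_spec)) {
    y <- notch_filter(y, fs, filter_spec)
    y <- bandpass_filter(y, fs, filter_spec)
  }
  wavelet_denoise(y, wavelet_config)
}

#' Denoise every channel of a recording
#'
#' @param rec A [recording()].
#' @inheritParams denoise
#' @return A new `recording` with denoised channels; attribute `thresholds`
#'   holds the per-channel SURE thresholds (channels x levels).
#' @export
denoise_recording <- function(rec, filter_spec = compen::filter_spec(),
                              wavelet_config = compen::wavelet_config()) {
  stopifnot(inherits(rec, "recording"))
  data <- rec$data
  th <- matrix(NA_real_, nrow(data), wavelet_config$level,
               dimnames = list(rec$channel_labels,
                               paste0("cD", seq_len(wavelet_config$level))))
  for (ch in seq_len(nrow(data))) {
    y <- denoise(data[ch, ], rec$fs, filter_spec, wavelet_config)
    th[ch, ] <- attr(y, "thresholds")
    data[ch, ] <- y
  }
  out <- recording(rec$subject_id, rec$gender, rec$emotion, data, rec$fs,
                   rec$channel_labels)
  attr(out, "thresholds") <- th
  out
}

#' Segment a series into fixed-length trials
#'
#' Takes the first `n_trials` contiguous non-overlapping windows of
#' `window_s` seconds from the start of the series (10 s at 128 Hz gives
#' the 1280-sample trial used throughout the analysis).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds.
#' @param n_trials Number of windows.
#' @return List of numeric vectors, each of length `window_s * fs`, with
#'   attribute `trial_index` set on each element.
#' @export
segment_trials <- function(x, fs, window_s = 10, n_trials = 3) {
  len <- as.integer(round(window_s * fs))
  need <- len * n_trials
  if (length(x) < need)
    stop_compen("insufficient samples for segmentation: need ", need,
                " (", n_trials, " x ", len, "), have ", length(x))
  lapply(seq_len(n_trials), function(i) {
    seg <- x[((i - 1L) * len + 1L):(i * len)]
    attr(seg, "trial_index") <- i
    seg
  })
}

#' Segment every channel of a recording into labelled trial segments
#'
#' @param rec A [recording()].
#' @inheritParams segment_trials
#' @return List of trial segments; each element is a list with `samples`,
#'   `channel`, `trial_index`, `subject_id`, `gender`, `emotion`.
#' @export
segment_recording <- function(rec, window_s = 10, n_trials = 3) {
  stopifnot(inherits(rec, "recording"))
  out <- list()
  for (ch in seq_len(nrow(rec$data))) {
    segs <- segment_trials(rec$data[ch, ], rec$fs, window_s, n_trials)
    for (s in segs) {
      out[[length(out) + 1L]] <- list(
        samples = as.numeric(s), channel = rec$channel_labels[ch],
        trial_index = attr(s, "trial_index"), subject_id = rec$subject_id,
        gender = rec$gender, emotion = rec$emotion)
    }
  }
  out
}
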