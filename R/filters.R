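# Conventional filtering: 50 Hz notch + Butterworth band limiting, applied
# zero-phase (forward-backward). Filter design is delegated to
# signal::butter; the zero-phase application is implemented here with odd
# reflection padding and steady-state initial conditions so that DC
# rejection and phase symmetry hold to numerical precision even for the very
# low 0.5 Hz corner (where naive forward-backward filtering leaves
# transients lasting thousands of samples).

#' Filter specification for the conventional preprocessing stage
#'
#' @param notch_freq Power-line frequency to remove, Hz.
#' @param notch_q Notch quality factor; the stopband width is
#'   `notch_freq / notch_q` Hz.
#' @param band_low Highpass corner, Hz.
#' @param band_high Lowpass corner, Hz. At `fs = 128` this equals Nyquist,
#'   where a lowpass is vacuous; the lowpass branch is applied only when
#'   `band_high < fs / 2`.
#' @param order Butterworth order for the band filter (even, >= 2).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 35,
                        band_low = 0.5, band_high = 64, order = 4) {
  if (band_low <= 0 || band_low >= band_high)
    stop_compen("need 0 < band_low < band_high")
  if (order < 2 || order %% 2 != 0)
    stop_compen("'order' must be even and >= 2")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 band_low = band_low, band_high = band_high, order = order),
            class = "filter_spec")
}

# Steady-state initial filter state for a unit-amplitude input
# (direct form II transposed), the standard companion-matrix solve.
.lfilter_zi <- function(b, a) {
  nf <- max(length(b), length(a))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  if (nf == 1L) return(numeric(0))
  comp <- rbind(-a[-1], cbind(diag(nf - 2L), numeric(nf - 2L)))
  solve(diag(nf - 1L) - t(comp), b[-1] - a[-1] * b[1])
}

# IIR filter, direct form II transposed, with initial state.
.iir <- function(b, a, x, zi = NULL) {
  nf <- max(length(b), length(a))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  z <- if (is.null(zi)) numeric(nf - 1L) else zi
  y <- numeric(length(x))
  bs <- b[-1]; as_ <- a[-1]
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    z <- c(z[-1], 0) + bs * x[i] - as_ * y[i]
  }
  y
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter twice (forward, then time-reversed), with odd
#' reflection padding and steady-state initial conditions, giving zero phase
#' distortion and squared magnitude response.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric series.
#' @param padlen Reflection padding length (capped at `length(x) - 1`).
#' @return Filtered series, same length as `x`.
#' @keywords internal
#' @noRd
.filtfilt <- function(b, a, x, padlen = 1024L) {
  n <- length(x)
  nf <- max(length(b), length(a))
  if (n <= 3L * (nf - 1L))
    stop_compen("series too short for zero-phase padding: ", n,
                " samples with a ", nf - 1L, "-order filter")
  np <- min(n - 1L, as.integer(padlen))
  xe <- c(2 * x[1] - rev(x[2:(np + 1L)]), x,
          2 * x[n] - rev(x[(n - np):(n - 1L)]))
  zi <- .lfilter_zi(b, a)
  y <- .iir(b, a, xe, zi * xe[1])
  y <- rev(.iir(b, a, rev(y), zi * y[length(y)]))
  y[(np + 1L):(np + n)]
}

#' Notch filter for power-line interference
#'
#' Second-order Butterworth bandstop centred on `spec$notch_freq`, applied
#' zero-phase. Attenuation at the line frequency exceeds 20 dB while
#' passband frequencies a few Hz away are essentially untouched.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  if (fs <= 2 * spec$notch_freq)
    stop_compen("'fs' must exceed twice the notch frequency")
  bw <- spec$notch_freq / spec$notch_q
  wl <- (spec$notch_freq - bw / 2) / (fs / 2)
  wh <- (spec$notch_freq + bw / 2) / (fs / 2)
  bf <- signal::butter(2, c(wl, wh), type = "stop")
  .filtfilt(bf$b, bf$a, x)
}

#' Butterworth band-limiting filter
#'
#' Zero-phase Butterworth highpass at `band_low`; a lowpass at `band_high`
#' is composed in only when `band_high < fs / 2` (at 128 Hz sampling the
#' 64 Hz upper edge equals Nyquist and the lowpass is vacuous). DC is
#' removed by the highpass branch.
#'
#' @inheritParams notch_filter
#' @return Filtered series.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (spec$band_high > fs / 2)
    stop_compen("'band_high' must not exceed Nyquist (fs/2)")
  hp <- signal::butter(spec$order, spec$band_low / (fs / 2), type = "high")
  y <- .filtfilt(hp$b, hp$a, x)
  if (spec$band_high < fs / 2) {
    lp <- signal::butter(spec$order, spec$band_high / (fs / 2), type = "low")
    y <- .filtfilt(lp$b, lp$a, y)
  }
  y
}
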