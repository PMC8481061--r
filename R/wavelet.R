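# Discrete wavelet transform with the Symlet-9 filter bank, plus SURE soft
# thresholding. No DWT is available among the installed packages, so the
# transform is implemented here: zero-extension analysis/synthesis with full
# coefficient bookkeeping, which makes the transform an exact isometry
# (coefficient energy equals signal energy) and perfectly invertible at any
# signal length, odd or even.

# Symlet-9 decomposition lowpass filter (18 taps, standard published values).
SYM9_DEC_LO <- c(
  0.0014009155259146807, 0.0006197808889855868, -0.013271967781817119,
  -0.01152821020767923, 0.03022487885827568, 0.0005834627461258068,
  -0.05456895843083407, 0.238760914607303, 0.717897082764412,
  0.6173384491409358, 0.035272488035271894, -0.19155083129728512,
  -0.018233770779395985, 0.06207778930288603, 0.008859267493400484,
  -0.010264064027633142, -0.0004731544986800831, 0.0010694900329086053)

.wavelet_bank <- function(name) {
  if (!identical(name, "sym9"))
    stop_compen("unknown wavelet name '", name, "' (only \"sym9\" is provided)")
  lo <- SYM9_DEC_LO
  m <- length(lo)
  hi <- (-1)^(seq_len(m) - 1) * rev(lo)   # quadrature mirror filter
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), len = m)
}

#' Wavelet configuration
#'
#' Dyadic DWT settings: wavelet name, decomposition level, and the
#' thresholding rule used by the denoiser. The dilation and translation
#' bases (`a0 = 2`, `b0 = 1`) define the standard dyadic grid and are fixed.
#'
#' @param wavelet_name Wavelet family member; `"sym9"`.
#' @param level Decomposition depth (>= 1); the signal must be at least
#'   `2^level` samples long.
#' @param threshold_rule `"sure"` (per-level Stein unbiased risk estimate) or
#'   `"none"` (thresholds forced to zero, denoiser becomes the identity on
#'   the wavelet stage).
#' @param threshold_mode Shrinkage mode; `"soft"`.
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(wavelet_name = "sym9", level = 4,
                           threshold_rule = c("sure", "none"),
                           threshold_mode = "soft") {
  threshold_rule <- match.arg(threshold_rule)
  threshold_mode <- match.arg(threshold_mode, "soft")
  if (level < 1) stop_compen("'level' must be >= 1")
  .wavelet_bank(wavelet_name)  # validates the name
  structure(list(wavelet_name = wavelet_name, level = as.integer(level),
                 a0 = 2, b0 = 1,
                 threshold_rule = threshold_rule,
                 threshold_mode = threshold_mode),
            class = "wavelet_config")
}

# Full (zero-extended) convolution via FFT.
.conv_full <- function(x, h) {
  n <- length(x); m <- length(h)
  nn <- n + m - 1L
  np <- stats::nextn(nn, 2)
  y <- fft(fft(c(x, numeric(np - n))) * fft(c(h, numeric(np - m))),
           inverse = TRUE)
  Re(y)[seq_len(nn)] / np
}

.dwt_step <- function(x, bank) {
  ya <- .conv_full(x, bank$dec_lo)
  yd <- .conv_full(x, bank$dec_hi)
  idx <- seq(2L, length(ya), by = 2L)
  list(a = ya[idx], d = yd[idx])
}

.idwt_step <- function(a, d, bank, n_out) {
  up <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(2L, length(u), by = 2L)] <- cf
    u
  }
  y <- .conv_full(up(a), bank$rec_lo) + .conv_full(up(d), bank$rec_hi)
  y[bank$len:(bank$len + n_out - 1L)]
}

#' Dyadic discrete wavelet transform
#'
#' Decomposes a series into `level` detail coefficient sets `cD1` (finest)
#' through `cD<level>` and one approximation set `cA<level>`. The transform
#' is orthonormal: total coefficient energy equals signal energy, and
#' [dwt_reconstruct()] inverts it exactly.
#'
#' @param x Numeric series, length >= `2^level`.
#' @param config A [wavelet_config()].
#' @return An object of class `wavelet_decomposition` with elements `approx`
#'   (cA at the deepest level), `details` (list `cD1..cD<level>`), `config`,
#'   and `original_length`.
#' @export
dwt_decompose <- function(x, config = wavelet_config()) {
  if (!all(is.finite(x))) stop_compen("'x' contains non-finite values")
  if (length(x) < 2^config$level)
    stop_compen("signal too short: ", length(x), " samples for level ",
                config$level, " (need >= ", 2^config$level, ")")
  bank <- .wavelet_bank(config$wavelet_name)
  details <- vector("list", config$level)
  lengths <- integer(config$level)
  cur <- as.numeric(x)
  for (lev in seq_len(config$level)) {
    lengths[lev] <- length(cur)
    st <- .dwt_step(cur, bank)
    details[[lev]] <- st$d
    cur <- st$a
  }
  names(details) <- paste0("cD", seq_len(config$level))
  structure(list(approx = cur, details = details, config = config,
                 level_lengths = lengths, original_length = length(x)),
            class = "wavelet_decomposition")
}

#' Inverse dyadic discrete wavelet transform
#'
#' @param decomp A `wavelet_decomposition` from [dwt_decompose()].
#' @return Numeric series of length `decomp$original_length`.
#' @export
dwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  bank <- .wavelet_bank(decomp$config$wavelet_name)
  cur <- decomp$approx
  for (lev in rev(seq_along(decomp$details)))
    cur <- .idwt_step(cur, decomp$details[[lev]], bank,
                      decomp$level_lengths[lev])
  cur
}

#' SURE threshold for one detail coefficient level
#'
#' Minimizes Stein's unbiased risk estimate for soft thresholding,
#' `SURE(t) = n - 2 * #\{|c_i| <= t\} + sum(min(c_i^2, t^2))`, over the
#' candidate set of observed coefficient magnitudes (plus zero). The noise
#' scale is estimated per level as `median(|c|) / 0.6745` and the threshold
#' is returned on the original coefficient scale.
#'
#' @param coeffs Numeric coefficient vector for one detail level.
#' @param sigma Noise standard deviation used to normalize the
#'   coefficients. Default `NULL` estimates it from `coeffs` itself as
#'   `median(|coeffs|) / 0.6745`; the denoiser instead passes the estimate
#'   from the finest detail level, where noise dominates (a homogeneous
#'   signal-bearing band normalized by its own spread would look like unit
#'   noise to the risk estimate and be zeroed wholesale).
#' @return Threshold value (scalar, >= 0).
#' @export
sure_threshold <- function(coeffs, sigma = NULL) {
  if (length(coeffs) == 0) stop_compen("empty coefficient set")
  if (is.null(sigma)) sigma <- median(abs(coeffs)) / 0.6745
  if (sigma == 0) return(0)
  cn <- sort(abs(coeffs / sigma))
  n <- length(cn)
  cn2 <- cn^2
  # risk at t = 0 and at each observed magnitude (evaluated where the
  # piecewise-smooth risk can attain its minimum)
  cand <- c(0, cn)
  csum <- c(0, cumsum(cn2))
  k <- c(0, seq_len(n))  # #{|c_i| <= t} at each candidate
  # sum(min(c_i^2, t^2)) = sum_{|c_i| <= t} c_i^2 + t^2 * #{|c_i| > t}
  risk <- n - 2 * k + csum[k + 1] + cand^2 * (n - k)
  cand[which.min(risk)] * sigma
}

#' Soft thresholding
#'
#' `sign(c) * max(|c| - t, 0)`; vectorized over `c`.
#'
#' @param c Coefficient(s).
#' @param t Threshold (>= 0).
#' @return Shrunk coefficient(s).
#' @export
soft_threshold <- function(c, t) {
  if (any(t < 0)) stop_compen("'t' must be >= 0")
  sign(c) * pmax(abs(c) - t, 0)
}

#' Wavelet shrinkage denoising
#'
#' Decomposes with [dwt_decompose()], soft-thresholds each detail level at
#' its own SURE threshold (the approximation band is never thresholded), and
#' reconstructs. The noise standard deviation is estimated once from the
#' finest detail level (`median(|cD1|) / 0.6745`), where noise dominates,
#' and shared by all levels' risk estimates -- thresholds remain per level.
#' With `threshold_rule = "none"` the stage is the identity.
#'
#' @param x Numeric series.
#' @param config A [wavelet_config()].
#' @return Denoised series, same length as `x`, with attribute `thresholds`
#'   (the per-level thresholds applied).
#' @export
wavelet_denoise <- function(x, config = wavelet_config()) {
  dec <- dwt_decompose(x, config)
  th <- numeric(length(dec$details))
  names(th) <- names(dec$details)
  if (config$threshold_rule == "sure") {
    sigma <- median(abs(dec$details[[1L]])) / 0.6745
    for (lev in seq_along(dec$details)) {
      th[lev] <- sure_threshold(dec$details[[lev]], sigma)
      dec$details[[lev]] <- soft_threshold(dec$details[[lev]], th[lev])
    }
  }
  out <- dwt_reconstruct(dec)
  attr(out, "thresholds") <- th
  out
}
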