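# Feature extraction: Hurst exponent by rescaled-range analysis,
# amplitude-aware permutation entropy (AAPE), and the fused
# complexity-entropy (CompEn) feature table.

#' Rescaled range of a series
#'
#' On the mean-centred cumulative sum Y of `x`, `R = max(Y) - min(Y)`;
#' `S` is the population standard deviation of `x`. `R/S` is scale
#' invariant.
#'
#' @param x Numeric series, length >= 2.
#' @return List with elements `R` and `S`.
#' @export
rescaled_range <- function(x) {
  if (length(x) < 2) stop_compen("'x' must have length >= 2")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0)
    stop_compen("degenerate input: constant series has zero standard deviation")
  y <- cumsum(x - mean(x))
  list(R = max(y) - min(y), S = s)
}

# Expected R/S of an iid Gaussian series of length T (Anis-Lloyd with the
# Peters finite-sample factor); used to de-bias the regression estimator.
.expected_rs <- function(T) {
  g <- if (T <= 340) {
    gamma((T - 1) / 2) / (sqrt(pi) * gamma(T / 2))
  } else {
    1 / sqrt(T * pi / 2)
  }
  i <- seq_len(T - 1)
  (T - 0.5) / T * g * sum(sqrt((T - i) / i))
}

.hurst_result <- function(H, scales, rs_values, method) {
  structure(list(H = H, scales = scales, rs_values = rs_values,
                 method = method), class = "hurst_result")
}

#' @export
print.hurst_result <- function(x, ...) {
  cat(sprintf("<hurst_result> H = %.4f (%s, %d scale%s)\n", x$H, x$method,
              length(x$scales), if (length(x$scales) == 1) "" else "s"))
  invisible(x)
}

#' Single-scale Hurst exponent
#'
#' The literal one-window estimator `H = log(R/S) / log(T)` with
#' `T = length(x)`. Provided for fidelity to the printed formula; it is
#' scale-degenerate (one point, no regression) and biased, and is not the
#' pipeline default — see [hurst_rs()].
#'
#' @param x Numeric series.
#' @return A `hurst_result` with `method = "printed_single_scale"`.
#' @export
hurst_printed <- function(x) {
  rs <- rescaled_range(x)
  T <- length(x)
  .hurst_result(log(rs$R / rs$S) / log(T), T, rs$R / rs$S,
                "printed_single_scale")
}

#' Hurst exponent by multi-scale rescaled-range regression
#'
#' Partitions `x` into non-overlapping subseries at dyadic scales
#' `T = min_scale, 2*min_scale, ...` up to `length(x)/2`, averages R/S
#' across subseries at each scale, and estimates H as the least-squares
#' slope of `log(mean R/S)` on `log(T)`. By default the regression is
#' de-biased by subtracting the Anis-Lloyd-Peters expected `log(R/S)` of an
#' iid series at each scale and adding back 0.5 -- without this correction
#' the small-sample estimator overshoots badly at low H (bias +0.10 at
#' H = 0.3, n = 1280). This is the pipeline default estimator.
#'
#' @param x Numeric series, length >= `4 * min_scale`.
#' @param min_scale Smallest subseries length.
#' @param correct Apply the expected-R/S small-sample correction.
#' @return A `hurst_result` with `method = "rs_regression"`. Estimates above
#'   1 (trended data) are returned as is, not clipped.
#' @export
hurst_rs <- function(x, min_scale = 8, correct = TRUE) {
  n <- length(x)
  scales <- min_scale * 2^(0:floor(log2(n / min_scale)))
  scales <- scales[scales <= n / 2]
  if (length(scales) < 3)
    stop_compen("fewer than 3 usable scales (series length ", n,
                ", min_scale ", min_scale, ")")
  # windowed R/S fully vectorized from global cumulative sums: within a
  # window starting at i0, the centred cumulative sum is
  # C[i0+i] - C[i0] - i * window_mean
  C1 <- c(0, cumsum(x))
  C2 <- c(0, cumsum(x^2))
  mean_rs <- vapply(scales, function(T) {
    nw <- n %/% T
    i0 <- (seq_len(nw) - 1L) * T
    mu <- (C1[i0 + T + 1L] - C1[i0 + 1L]) / T
    v <- (C2[i0 + T + 1L] - C2[i0 + 1L]) / T - mu^2
    s <- sqrt(pmax(v, 0))
    Y <- matrix(C1[rep(i0, each = T) + seq_len(T) + 1L], T, nw) -
      rep(C1[i0 + 1L], each = T) - outer(seq_len(T), mu)
    hi <- Y[cbind(max.col(t(Y), ties.method = "first"), seq_len(nw))]
    lo <- Y[cbind(max.col(t(-Y), ties.method = "first"), seq_len(nw))]
    ok <- s > 1e-12 * max(abs(x))
    if (!any(ok)) return(NA_real_)
    mean((hi[ok] - lo[ok]) / s[ok])
  }, numeric(1))
  if (any(!is.finite(mean_rs)))
    stop_compen("degenerate input: no usable windows at some scale")
  lt <- log(scales)
  lrs <- log(mean_rs)
  if (correct) {
    le <- log(vapply(scales, .expected_rs, numeric(1)))
    H <- 0.5 + unname(coef(lm(I(lrs - le) ~ lt))[2])
  } else {
    H <- unname(coef(lm(lrs ~ lt))[2])
  }
  .hurst_result(H, scales, mean_rs, "rs_regression")
}

#' Ordinal motif index of an embedded vector
#'
#' Index (0 to `d! - 1`, Lehmer code) of the permutation that sorts `v`
#' ascending. Ties are broken stably by order of occurrence, so e.g.
#' `(2, 2, 1)` maps to the same motif as `(2, 3, 1)`.
#'
#' @param v Numeric vector of length d.
#' @param tie_rule Tie-breaking policy; only `"stable"` is defined.
#' @return Integer motif index in `0:(factorial(d) - 1)`.
#' @export
ordinal_motif <- function(v, tie_rule = "stable") {
  match.arg(tie_rule, "stable")
  d <- length(v)
  ord <- order(v)          # stable: ties by occurrence order
  idx <- 0L
  for (i in seq_len(d - 1L)) {
    idx <- idx + sum(ord[(i + 1L):d] < ord[i]) * factorial(d - i)
  }
  as.integer(idx)
}

#' AAPE configuration
#'
#' @param d Embedding dimension (>= 2).
#' @param l Time delay (>= 1). Default 1: with equiprobable motifs the
#'   entropy is maximal at unit delay.
#' @param A Amplitude-balance coefficient in \[0, 1\]: weight of the mean
#'   absolute amplitude term against the mean absolute successive-difference
#'   term. `A = 1` is pure amplitude weighting, `A = 0` pure difference
#'   weighting.
#' @param tie_rule Ordinal tie-breaking policy (`"stable"`).
#' @return A list of class `aape_config`.
#' @export
aape_config <- function(d = 4L, l = 1L, A = 0.5, tie_rule = "stable") {
  if (d < 2) stop_compen("'d' must be >= 2")
  if (l < 1) stop_compen("'l' must be >= 1")
  if (A < 0 || A > 1) stop_compen("'A' must be in [0, 1]")
  match.arg(tie_rule, "stable")
  structure(list(d = as.integer(d), l = as.integer(l), A = A,
                 tie_rule = tie_rule), class = "aape_config")
}

#' Amplitude-aware permutation entropy
#'
#' Shannon entropy (nats) of the ordinal-motif distribution where each
#' embedded vector `(x_i, x_{i+l}, ..., x_{i+(d-1)l})` contributes weight
#' `w_i = (A/d) * sum(|x|) + ((1-A)/(d-1)) * sum(|successive differences|)`
#' instead of a unit count. Motif probabilities are the weight shares;
#' ties in the ordinal ranking are broken stably by occurrence order.
#' Bounded by `log(d!)`; zero iff a single motif carries all weight.
#'
#' @param x Numeric series with `length(x) > d * l`.
#' @param config An [aape_config()]; alternatively pass `d`, `l`, `A`.
#' @param d,l,A Shorthand overrides for the config values.
#' @return Entropy in nats.
#' @export
aape <- function(x, config = aape_config(), d = NULL, l = NULL, A = NULL) {
  if (!is.null(d) || !is.null(l) || !is.null(A))
    config <- aape_config(d %||% config$d, l %||% config$l, A %||% config$A)
  d <- config$d; l <- config$l; A <- config$A
  n <- length(x)
  if (n <= d * l) stop_compen("series length must exceed d * l")
  if (max(x) == min(x))
    stop_compen("degenerate input: constant series carries no motif weight")
  m <- n - (d - 1L) * l
  emb <- vapply(0:(d - 1L), function(k) x[(1L + k * l):(m + k * l)],
                numeric(m))
  if (m == 1L) emb <- matrix(emb, nrow = 1L)
  # stable ranks: rank of column k = #{j : v_j < v_k, or v_j == v_k and j < k}
  ranks <- matrix(0L, m, d)
  for (k in seq_len(d)) {
    for (j in seq_len(d)) {
      if (j == k) next
      lt <- emb[, j] < emb[, k]
      if (j < k) lt <- lt | (emb[, j] == emb[, k])
      ranks[, k] <- ranks[, k] + lt
    }
  }
  motif <- as.integer(ranks %*% d^(0:(d - 1L)))  # injective motif key
  w <- (A / d) * rowSums(abs(emb))
  if (d > 1L)
    w <- w + ((1 - A) / (d - 1)) *
      rowSums(abs(emb[, -1L, drop = FALSE] - emb[, -d, drop = FALSE]))
  tw <- sum(w)
  if (tw == 0)
    stop_compen("degenerate input: all motif weights are zero")
  p <- as.numeric(tapply(w, motif, sum)) / tw
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Classical permutation entropy (unit motif weights)
#'
#' Companion to [aape()]: the A-independent ordinal entropy that counts
#' motifs with unit weight, hence is blind to amplitude. Used to demonstrate
#' the amplitude sensitivity that AAPE adds.
#'
#' @inheritParams aape
#' @return Entropy in nats.
#' @export
perm_entropy <- function(x, config = aape_config(), d = NULL, l = NULL) {
  if (!is.null(d) || !is.null(l))
    config <- aape_config(d %||% config$d, l %||% config$l, config$A)
  d <- config$d; l <- config$l
  n <- length(x)
  if (n <= d * l) stop_compen("series length must exceed d * l")
  m <- n - (d - 1L) * l
  emb <- vapply(0:(d - 1L), function(k) x[(1L + k * l):(m + k * l)],
                numeric(m))
  if (m == 1L) emb <- matrix(emb, nrow = 1L)
  ranks <- matrix(0L, m, d)
  for (k in seq_len(d)) {
    for (j in seq_len(d)) {
      if (j == k) next
      lt <- emb[, j] < emb[, k]
      if (j < k) lt <- lt | (emb[, j] == emb[, k])
      ranks[, k] <- ranks[, k] + lt
    }
  }
  motif <- as.integer(ranks %*% d^(0:(d - 1L)))
  p <- as.numeric(table(motif)) / m
  -sum(p * log(p))
}

#' Fuse complexity and irregularity feature vectors
#'
#' Concatenates a named Hurst feature vector and a named AAPE feature vector
#' from the same instance into the combined complexity-entropy (CompEn)
#' feature vector. Names must not collide.
#'
#' @param hur_features,aape_features Named numeric vectors.
#' @return Named numeric vector `[hur_features, aape_features]`.
#' @export
compen_fuse <- function(hur_features, aape_features) {
  if (length(hur_features) && length(aape_features)) {
    if (is.null(names(hur_features)) || is.null(names(aape_features)))
      stop_compen("both feature vectors must be named")
    if (any(names(hur_features) %in% names(aape_features)))
      stop_compen("feature name collision between the two families")
  }
  c(hur_features, aape_features)
}

#' Build the instances x features table from trial segments
#'
#' One instance per subject x trial (features concatenated across all
#' emotions and channels, the default) or per subject x trial x emotion.
#' Columns are ordered channel-major, emotion-minor within each feature
#' family; for the CompEn layout the Hurst block precedes the AAPE block.
#' Input segment order is irrelevant. Missing subject x emotion x channel x
#' trial cells are an error naming the missing cells.
#'
#' @param segments List of labelled segments from [segment_recording()].
#' @param layout `"COMPEN"`, `"HUR"` or `"AAPE"`.
#' @param aape_config An [aape_config()].
#' @param hurst_min_scale,hurst_correct Passed to [hurst_rs()].
#' @param instance_unit `"subject_trial"` (default) or
#'   `"subject_trial_emotion"`.
#' @return An object of class `feature_table`: `matrix` (instances x
#'   features), `feature_names`, `labels` (gender factor), `layout`, plus
#'   `instances` (data frame of subject/trial identifiers).
#' @export
build_feature_table <- function(segments,
                                layout = c("COMPEN", "HUR", "AAPE"),
                                aape_config = compen::aape_config(),
                                hurst_min_scale = 8, hurst_correct = TRUE,
                                instance_unit = c("subject_trial",
                                                  "subject_trial_emotion")) {
  layout <- match.arg(layout)
  instance_unit <- match.arg(instance_unit)
  meta <- data.frame(
    subject = vapply(segments, `[[`, "", "subject_id"),
    gender = vapply(segments, `[[`, "", "gender"),
    emotion = vapply(segments, `[[`, "", "emotion"),
    channel = vapply(segments, function(s) as.character(s$channel), ""),
    trial = vapply(segments, function(s) as.integer(s$trial_index), 0L),
    stringsAsFactors = FALSE)
  subjects <- sort(unique(meta$subject))
  emotions <- sort(unique(meta$emotion))   # alphabetical: order is
  channels <- sort(unique(meta$channel))   # input-order invariant
  trials <- sort(unique(meta$trial))
  # completeness: every subject x emotion x channel x trial cell present
  want <- expand.grid(subject = subjects, emotion = emotions,
                      channel = channels, trial = trials,
                      stringsAsFactors = FALSE)
  key <- function(df) paste(df$subject, df$emotion, df$channel, df$trial,
                            sep = "|")
  missing <- setdiff(key(want), key(meta))
  if (length(missing))
    stop_compen("missing segment cells (subject|emotion|channel|trial): ",
                paste(head(missing, 5), collapse = ", "),
                if (length(missing) > 5) sprintf(" ... (%d total)",
                                                 length(missing)) else "")
  seg_lookup <- split(seq_along(segments), key(meta))
  need_hur <- layout %in% c("HUR", "COMPEN")
  need_aape <- layout %in% c("AAPE", "COMPEN")

  cell_features <- function(subject, trial, emos) {
    hur <- aap <- numeric(0)
    for (ch in channels) for (em in emos) {
      i <- seg_lookup[[paste(subject, em, ch, trial, sep = "|")]][1]
      x <- segments[[i]]$samples
      tag <- if (length(emos) > 1) paste(ch, em, sep = "_") else ch
      if (need_hur)
        hur[paste0("Hur_", tag)] <-
          hurst_rs(x, hurst_min_scale, hurst_correct)$H
      if (need_aape)
        aap[paste0("AAPE_", tag)] <- aape(x, aape_config)
    }
    switch(layout, HUR = hur, AAPE = aap, COMPEN = compen_fuse(hur, aap))
  }

  if (instance_unit == "subject_trial") {
    inst <- expand.grid(trial = trials, subject = subjects,
                        stringsAsFactors = FALSE)[, c("subject", "trial")]
    rows <- lapply(seq_len(nrow(inst)), function(i)
      cell_features(inst$subject[i], inst$trial[i], emotions))
  } else {
    inst <- expand.grid(emotion = emotions, trial = trials,
                        subject = subjects, stringsAsFactors = FALSE)
    inst <- inst[, c("subject", "trial", "emotion")]
    rows <- lapply(seq_len(nrow(inst)), function(i)
      cell_features(inst$subject[i], inst$trial[i], inst$emotion[i]))
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  gender <- meta$gender[match(inst$subject, meta$subject)]
  structure(list(matrix = mat, feature_names = colnames(mat),
                 labels = factor(gender, levels = c("female", "male")),
                 layout = layout, instances = inst),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d instances x %d features (%d female, %d male)\n",
              x$layout, nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "female"), sum(x$labels == "male")))
  invisible(x)
}

#' Long-format per-segment feature values
#'
#' One row per subject x trial x emotion x channel segment with the Hurst
#' and AAPE values, the observational unit used by the two-way ANOVA stage
#' (channels as replicates) and exported so that routine follow-up tests can
#' be run in any statistics package.
#'
#' @inheritParams build_feature_table
#' @return Data frame with columns `value_hur`, `value_aape`, `gender`,
#'   `emotion`, `subject`, `trial`, `channel`.
#' @export
feature_long <- function(segments, aape_config = compen::aape_config(),
                         hurst_min_scale = 8, hurst_correct = TRUE) {
  rows <- lapply(segments, function(s) {
    data.frame(value_hur = hurst_rs(s$samples, hurst_min_scale,
                                    hurst_correct)$H,
               value_aape = aape(s$samples, aape_config),
               gender = s$gender, emotion = s$emotion,
               subject = s$subject_id, trial = s$trial_index,
               channel = as.character(s$channel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
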