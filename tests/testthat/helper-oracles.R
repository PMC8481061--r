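# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# AAPE by direct nested loops over embedded vectors; motif identity keyed by
# the full stable ordering permutation.
aape_brute <- function(x, d, l, A) {
  n <- length(x)
  keys <- character(0)
  weights <- numeric(0)
  for (i in 1:(n - (d - 1) * l)) {
    v <- x[i + (0:(d - 1)) * l]
    key <- paste(order(v), collapse = "-")
    w_amp <- 0
    for (k in 1:d) w_amp <- w_amp + abs(v[k])
    w_diff <- 0
    if (d > 1) for (k in 2:d) w_diff <- w_diff + abs(v[k] - v[k - 1])
    w <- (A / d) * w_amp + ((1 - A) / (d - 1)) * w_diff
    keys <- c(keys, key)
    weights <- c(weights, w)
  }
  p <- tapply(weights, keys, sum) / sum(weights)
  p <- p[p > 0]
  -sum(p * log(p))
}

pe_brute <- function(x, d, l) {
  n <- length(x)
  keys <- vapply(1:(n - (d - 1) * l), function(i)
    paste(order(x[i + (0:(d - 1)) * l]), collapse = "-"), "")
  p <- table(keys) / length(keys)
  -sum(p * log(p))
}

# SURE risk minimizer by explicit evaluation at every candidate threshold.
sure_brute <- function(coeffs, sigma = NULL) {
  if (is.null(sigma)) sigma <- median(abs(coeffs)) / 0.6745
  if (sigma == 0) return(0)
  cn <- abs(coeffs / sigma)
  n <- length(cn)
  cand <- c(0, sort(cn))
  risk <- vapply(cand, function(t)
    n - 2 * sum(cn <= t) + sum(pmin(cn^2, t^2)), numeric(1))
  cand[which.min(risk)] * sigma
}

# AUC as the normalized Mann-Whitney U statistic over all pairs.
auc_brute <- function(y, scores) {
  sf <- scores[y == "female"]
  sm <- scores[y == "male"]
  tot <- 0
  for (a in sf) for (b in sm)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sf) * length(sm))
}

# kNN by all-pairs distances with stable tie handling.
knn_brute <- function(train_X, train_y, test_X, k) {
  sapply(seq_len(nrow(test_X)), function(i) {
    d <- sqrt(rowSums((train_X - matrix(test_X[i, ], nrow(train_X),
                                        ncol(train_X), byrow = TRUE))^2))
    nn <- order(d)[1:k]
    mean(train_y[nn] == "female")
  })
}

# SVM dual by projected gradient ascent on
#   max sum(alpha) - 0.5 * alpha' Q alpha,  0 <= alpha <= C, sum(alpha*y) = 0
# with Q = (y y') * K. Good enough on small separable toys with many steps.
svm_dual_pg <- function(K, y, C, iters = 20000, lr = 1e-3) {
  n <- length(y)
  Q <- outer(y, y) * K
  alpha <- rep(min(C, 1e-3), n)
  for (it in seq_len(iters)) {
    g <- 1 - Q %*% alpha
    alpha <- alpha + lr * as.numeric(g)
    # project onto the box and the hyperplane sum(alpha * y) = 0
    alpha <- pmin(pmax(alpha, 0), C)
    for (j in 1:50) {
      viol <- sum(alpha * y) / n
      alpha <- pmin(pmax(alpha - viol * y, 0), C)
      if (abs(sum(alpha * y)) < 1e-10) break
    }
  }
  alpha
}

svm_decision_oracle <- function(train_X, y_pm, test_X, C, sigma) {
  rbf <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-d2 / (2 * sigma^2))
  }
  K <- rbf(train_X, train_X)
  alpha <- svm_dual_pg(K, y_pm, C)
  sv <- alpha > 1e-8
  margins <- which(alpha > 1e-6 & alpha < C - 1e-6)
  b <- mean(y_pm[margins] - (K %*% (alpha * y_pm))[margins])
  as.numeric(rbf(test_X, train_X) %*% (alpha * y_pm) + b)
}

# Balanced two-way ANOVA sums of squares via explicit least-squares
# projections onto nested effect-coded design subspaces.
anova_proj_brute <- function(values, gender, emotion) {
  g <- factor(gender); e <- factor(emotion)
  proj_rss <- function(X) {
    fit <- qr.fitted(qr(X), values)
    sum((values - fit)^2)
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X_full <- model.matrix(~ g * e)
  X_add <- model.matrix(~ g + e)
  X_g <- model.matrix(~ g)
  X_e <- model.matrix(~ e)
  list(ss_a = proj_rss(X_e) - proj_rss(X_add),
       ss_b = proj_rss(X_g) - proj_rss(X_add),
       ss_ab = proj_rss(X_add) - proj_rss(X_full),
       ss_err = proj_rss(X_full))
}

# Straightforward per-window R/S loop (no vectorization tricks).
rs_scales_loop <- function(x, min_scale = 8) {
  n <- length(x)
  scales <- min_scale * 2^(0:floor(log2(n / min_scale)))
  scales <- scales[scales <= n / 2]
  vapply(scales, function(T) {
    nw <- n %/% T
    mean(vapply(seq_len(nw), function(i) {
      seg <- x[((i - 1) * T + 1):(i * T)]
      s <- sqrt(mean((seg - mean(seg))^2))
      if (s == 0) return(NA_real_)
      y <- cumsum(seg - mean(seg))
      (max(y) - min(y)) / s
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
}

# Small artifact-free cohort used by several tests.
make_tiny_cohort <- function(seed = 1, n_channels = 2, duration_s = 30,
                             ...) {
  cohort_config(channel_labels = EMOTIV_LABELS[seq_len(n_channels)],
                duration_s = duration_s,
                artifact_params = list(line_amp = 0, drift_amp = 0,
                                       burst_rate = 0),
                seed = seed, ...)
}
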