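# Two-way ANOVA of gender x emotion and Tukey boxplot summaries.

#' Two-way ANOVA (gender x emotion)
#'
#' Balanced designs use the textbook cell-mean sums of squares (which
#' partition the total exactly); unbalanced designs use Type II sums of
#' squares via nested least-squares model comparisons, each main effect
#' adjusted for the other and the interaction adjusted for both. F tests use
#' the full-model error mean square.
#'
#' @param values Numeric response vector.
#' @param gender Factor-like, 2+ levels (factor A).
#' @param emotion Factor-like, 2+ levels (factor B).
#' @param alpha Significance level recorded in the table.
#' @return An object of class `anova_table`: data frame with rows `gender`,
#'   `emotion`, `gender:emotion`, `error` and columns `SS`, `df`, `MS`, `F`,
#'   `p`; attributes `balanced`, `ss_type`, `alpha`.
#' @export
two_way_anova <- function(values, gender, emotion, alpha = 0.05) {
  gender <- factor(gender)
  emotion <- factor(emotion)
  if (nlevels(gender) < 2 || nlevels(emotion) < 2)
    stop_compen("both factors need at least 2 levels")
  if (length(values) != length(gender) || length(values) != length(emotion))
    stop_compen("'values' and factors must have equal length")
  counts <- table(gender, emotion)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop_compen("empty design cell: gender '", levels(gender)[bad[1]],
                "' x emotion '", levels(emotion)[bad[2]], "'")
  }
  if (any(counts < 2))
    stop_compen("need >= 2 observations per cell")
  a <- nlevels(gender); b <- nlevels(emotion); n <- length(values)
  balanced <- length(unique(as.vector(counts))) == 1L

  if (balanced) {
    r <- counts[1, 1]
    grand <- mean(values)
    mA <- tapply(values, gender, mean)
    mB <- tapply(values, emotion, mean)
    mAB <- tapply(values, list(gender, emotion), mean)
    ss_a <- b * r * sum((mA - grand)^2)
    ss_b <- a * r * sum((mB - grand)^2)
    ss_ab <- r * sum((mAB - outer(mA, rep(1, b)) -
                        outer(rep(1, a), mB) + grand)^2)
    ss_err <- sum((values - mAB[cbind(gender, emotion)])^2)
    ss_type <- "balanced cell means"
  } else {
    rss <- function(formula) sum(lm(formula)$residuals^2)
    rss_full <- rss(values ~ gender * emotion)
    rss_add <- rss(values ~ gender + emotion)
    ss_a <- rss(values ~ emotion) - rss_add
    ss_b <- rss(values ~ gender) - rss_add
    ss_ab <- rss_add - rss_full
    ss_err <- rss_full
    ss_type <- "Type II"
  }
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), n - a * b)
  ss <- c(ss_a, ss_b, ss_ab, ss_err)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  tab <- data.frame(effect = c("gender", "emotion", "gender:emotion", "error"),
                    SS = ss, df = df, MS = ms, F = f, p = p,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("anova_table", "data.frame"),
            balanced = balanced, ss_type = ss_type, alpha = alpha)
}

#' Tukey boxplot summary per group
#'
#' Quartiles use linear interpolation of order statistics
#' (`stats::quantile` type 6), so for values 1..9 the quartiles are exactly
#' 2.5 and 7.5; whiskers extend to the most extreme observations within
#' 1.5 x IQR of the quartiles, and points beyond are listed as outliers.
#'
#' @param values Numeric vector.
#' @param group Factor-like grouping.
#' @return Data frame with one row per group: `group`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n`, and a list column `outliers`.
#' @export
group_summary <- function(values, group) {
  group <- factor(group)
  if (any(tapply(values, group, length) == 0) || length(values) == 0)
    stop_compen("all groups must be non-empty")
  res <- lapply(levels(group), function(g) {
    v <- values[group == g]
    if (length(v) == 1L) {
      q1 <- q3 <- med <- v
    } else {
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
      q1 <- q[1]; med <- q[2]; q3 <- q[3]
    }
    iqr <- q3 - q1
    lo <- v[v >= q1 - 1.5 * iqr]
    hi <- v[v <= q3 + 1.5 * iqr]
    out <- v[v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr]
    data.frame(group = g, median = med, q1 = q1, q3 = q3,
               whisker_low = min(lo), whisker_high = max(hi),
               n = length(v), outliers = I(list(out)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
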