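# Internal RNG plumbing. Every stochastic function takes an integer seed and
# runs in a local RNG scope, so callers' random streams are never disturbed
# and sub-streams can be split arithmetically per subject/emotion/channel.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so surrounding code's random stream is
#' untouched. With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and integer indices
#'
#' Splittable seeding: a fixed integer hash of `(seed, ...)` below 2^31, so
#' each subject x emotion x channel cell owns an independent, reproducible
#' sub-stream and adding subjects never perturbs existing ones.
#'
#' @param seed Parent integer seed.
#' @param ... Integer indices identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (v in idx) {
    # 48271: a classic Lehmer multiplier; arithmetic stays in double range
    h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_compen <- function(...) stop(..., call. = FALSE)
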