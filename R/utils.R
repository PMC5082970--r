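#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom cor sd var lm pf pt qf qt coef resid fft
#'   mvfft fitted quantile median
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a label
#'
#' A small deterministic integer hash so that per-subject and per-stage random
#' streams are independent but fully reproducible from one master seed.
#' The label is hashed with a 31-multiplier polynomial over its UTF-8 bytes and
#' combined with the master seed by a Lehmer step, all modulo 2^31 - 1.
#'
#' @param seed Master seed (integer-like scalar).
#' @param label Character scalar naming the stream (subject id, stage name).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  s <- (abs(as.numeric(seed)) %% m)
  v <- (s * 48271 + h * 16807 + 12345) %% m
  as.integer(if (v == 0) 1 else v)
}

# Evaluate expr under a seeded RNG, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Circularly shift a vector: element t of the result is x[t + lag] (wrapping).
circular_shift <- function(x, lag) {
  n <- length(x)
  if (n == 0L || lag %% n == 0) return(x)
  x[((seq_len(n) - 1 + lag) %% n) + 1]
}

# Sample skewness (used for the ICA sign convention).
skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# Pearson correlation between columns of a matrix and a vector, vectorized.
col_cor <- function(M, y) {
  My <- sweep(M, 2, colMeans(M))
  yc <- y - mean(y)
  as.vector(crossprod(My, yc)) / (sqrt(colSums(My^2)) * sqrt(sum(yc^2)))
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
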