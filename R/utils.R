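#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' never disturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' A fixed linear-congruential mix keeps every stochastic stage (fold
#' assignment, sampling, learners, Monte Carlo draws) on an independent but
#' fully reproducible stream below 2^31.
#'
#' @param seed Master integer seed.
#' @param index Stream index (any non-negative integer).
#' @return An integer seed in `[0, 2^31)`.
#' @keywords internal
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 69069 + as.numeric(index) * 104729 + 1
  as.integer(s %% m)
}

# Angle in degrees between two vectors; NA for zero-length input.
vec_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cs <- sum(a * b) / (na * nb)
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
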