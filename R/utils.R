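#' Run code under a fixed RNG state
#'
#' Evaluates `code` with the global RNG seeded at `seed`, restoring the
#' caller's RNG state afterwards so that seeded operations never perturb
#' each other's draws.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Derive an operation-specific seed
#'
#' Stream-splitting rule: each stochastic operation draws from its own
#' stream, seeded by `(seed * 2654435761 + hash(op)) mod (2^31 - 1)` where
#' `hash` is a base-31 polynomial over the operation name's bytes.  Adding
#' a new operation therefore never changes the draws of an existing one.
#'
#' @param op operation name (character scalar).
#' @param seed user-level integer seed.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
op_seed <- function(op, seed) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(op)) h <- (h * 31 + b) %% m
  as.integer(((seed %% m) * 69069 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic text formatting for file writers (byte-identical reruns)
num_fmt <- function(x) formatC(x, format = "g", digits = 12)
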