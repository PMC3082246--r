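#' Derive a child seed from a global seed and a salt string
#'
#' A single run-level seed drives a hierarchy of per-operation seeds so that
#' individual stages can be regenerated independently and deterministically.
#'
#' @param seed integer global seed.
#' @param salt character tag naming the operation.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% .Machine$integer.max)
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_histofunc <- function(...) stop(..., call. = FALSE)
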