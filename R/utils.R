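#' Derive a named substream seed from a master seed
#'
#' Stages of the pipeline (simulation, artifact injection, Monte-Carlo
#' integration, ...) each draw their randomness from a substream derived
#' deterministically from one master seed and a stage name, so that any stage
#' can be re-run in isolation and reproduce its output exactly.
#'
#' @param seed master integer seed.
#' @param name character stage name (e.g. `"simulate"`, `"artifacts"`).
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "simulate")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # polynomial string hash folded into the seed; all arithmetic kept in
  # double precision below 2^53, result reduced mod (2^31 - 1)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

#' Round half away from zero
#'
#' Weight standardization rounds to whole units with halves going away from
#' zero (so 69.5 kg -> 70 kg), unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# invlogit with guard against overflow
plogis_ <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# stop() with a condition class so callers/tests can target errors precisely
stop_svypath <- function(msg, class) {
  stop(structure(
    class = c(class, "svypath_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
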