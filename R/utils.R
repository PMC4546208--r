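#' Derive a reproducible sub-seed for a labelled RNG stream
#'
#' Each simulated output file (or logical output unit) gets its own RNG
#' stream, seeded deterministically from the master seed and a text label.
#' Adding samples to a cohort therefore never reshuffles the random draws of
#' previously generated samples.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the stream (e.g. `"meth_P3_T"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Run code under a labelled RNG stream without disturbing the caller's RNG.
with_stream <- function(seed, label, code) {
  withr::with_seed(stream_seed(seed, label), code)
}

# stop() with a consistent prefix
abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
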