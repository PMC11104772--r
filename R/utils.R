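#' @keywords internal
#' @noRd
stop_ciliaflow <- function(..., class = "ciliaflow_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

#' Derive a per-stage seed from a run seed
#'
#' Every pipeline stage draws its randomness from a seed derived
#' deterministically from the run seed and the stage name, so stages are
#' independently reproducible. The derivation is a fixed modular hash and
#' always returns a value in [1, 2^31 - 2].
#'
#' @param seed integer run seed.
#' @param stage character stage name (e.g. "roi", "noise").
#' @return a single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in 32-bit range
  h <- 17
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 69621 + h * 40692 + 1) %% (m - 1) + 1)
}

# Evaluate expr with a local RNG stream; global .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# TRUE when x is a single finite number strictly greater than lo
is_scalar_num <- function(x, lo = -Inf) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > lo
}
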