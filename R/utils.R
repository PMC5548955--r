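# Internal helpers shared across modules.

#' Derive a component-specific sub-seed from a master seed
#'
#' Stages of the pipeline draw their randomness from sub-seeds derived
#' deterministically from a single master seed, so that any stage can be
#' re-run in isolation and reproduce its output.  The derivation hashes the
#' component label into an offset and keeps the result inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed.
#' @param component character label of the pipeline component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (code in utf8ToInt(component)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library users' random streams are not clobbered.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round() uses banker's rounding; incidence percentages follow the
# round-half-away-from-zero convention instead.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
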