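# Seed handling. All stochastic entry points take an explicit seed and run
# inside with_seed(), which restores the caller's RNG state afterwards, so
# package calls never perturb a user's random stream.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state on exit. Used by every stochastic function in the package so that
#' results are reproducible without clobbering the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# deterministic substream seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
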