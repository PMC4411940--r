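# RNG helpers: every stochastic operation takes an explicit seed and leaves
# the caller's RNG state untouched.

#' @keywords internal
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

# Deterministic per-stream sub-seed derived from one global seed, so that
# adding a consumer never perturbs the draws of earlier ones. Kept within
# 32-bit integer range.
#' @keywords internal
sub_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 99991) * 100003 + stream * 7919
  as.integer(s %% 2147483647) + 1L
}
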