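# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All generators route their randomness through this so that one
# integer seed fully determines one simulated object.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct sub-seed per simulated object / named stream, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  offsets <- c(bulk = 11L, cells = 23L, cohort = 37L, module = 53L)
  off <- offsets[[stream]]
  (as.integer(seed) %% 1000000007L) * 2L + off
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_plagekit <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_plagekit(sprintf("`%s` must be a single finite number", name))
  }
}
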