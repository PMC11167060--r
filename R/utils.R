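# Internal helpers shared across modules.

# Deterministic sub-seed for a named artefact. Each generator draws from its
# own stream derived from (seed, artefact name), so adding a generator never
# perturbs the output of the others. Kept within [1, 2^31 - 2] (R integers
# are 32-bit).
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(seed)) %% m)
  for (b in utf8ToInt(name)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1L) + 1)
}

# Evaluate `expr` under the stream RNG without disturbing the caller's RNG
# state.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sign() that maps exact zero to 0L and returns integer.
sign_int <- function(x) as.integer(sign(x))

stop_panrenal <- function(...) stop(..., call. = FALSE)
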