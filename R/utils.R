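# Internal helpers shared across modules.

# sign with sign(0) = +1, so choices are deterministic even at dv == 0
# (a probability-zero event for continuous dv).
sign1 <- function(x) ifelse(x >= 0, 1, -1)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministically derive a sub-stream seed from a master seed; keeps results
# reproducible stage-by-stage without seed collisions. Always < 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 11 * offset) %% 2147483629)
}

stop_param <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
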