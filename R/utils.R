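# Internal utilities: seeded evaluation and stable seed derivation.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable integer hash combining a master seed with arbitrary small integers
# (grid row/col, epoch index, ...). All arithmetic stays below 2^53 so the
# result is exact in doubles and identical across platforms; the result is a
# valid 32-bit seed. Used so that per-tile streams are reproducible under
# partial regeneration of a scene.
derive_seed <- function(seed, ...) {
  p <- 2147483629 # prime < 2^31
  h <- (abs(as.numeric(seed)) %% p)
  for (k in c(...)) {
    h <- (h * 48271 + abs(as.numeric(k)) + 1) %% p
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
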