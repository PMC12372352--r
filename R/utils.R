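# Small internal helpers.

# Save/restore the global RNG state so seeded package functions do not
# perturb the caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# derive a reproducible 32-bit sub-seed from a base seed and an index
# (double arithmetic stays exact below 2^53, result fits in 32 bits)
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 747796405 * (as.numeric(i) %% 2654)) %% 2147483647)
}

# trapezoidal integral on a (possibly non-uniform) grid
.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
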