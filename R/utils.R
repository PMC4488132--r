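# internal helpers shared across modules

# generator layers, each with its own RNG stream
.flor_layers <- c("expression", "raw", "annotations", "sequences")

# Derive per-layer RNG seeds from a master seed so layers can be
# regenerated independently.  Seeds stay below 2^31 - 1.
.layer_seeds <- function(seed, layers = .flor_layers) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(layers))
  names(s) <- layers
  s
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# run expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
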