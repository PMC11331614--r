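#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel their randomness through
# this helper so results are reproducible from a single integer seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Derive a stream of child seeds from one parent seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}
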