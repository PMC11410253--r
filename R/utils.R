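# Internal helpers.

# A private RNG stream: draws advance their own saved state and leave the
# caller's global RNG untouched, so generators are pure functions of their
# seed argument regardless of surrounding code.
.seeded_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    res <- expr
    state <<- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
    res
  }
  list(
    unif = function(n, lo = 0, hi = 1) with_state(runif(n, lo, hi)),
    norm = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    int = function(n, k) with_state(sample.int(k, n, replace = TRUE)),
    sample_idx = function(k, n) with_state(sample.int(k, n)),
    perm = function(k) with_state(sample.int(k, k))
  )
}

# Derive a bounded child seed from (seed, tag) without consuming RNG state.
.child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 2654435 +
                sum(utf8ToInt(as.character(tag))) * 97) %% 2147483629)
}
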