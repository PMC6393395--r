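# internal helpers shared across modules

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic functions in the
# package route their randomness through this so that a seed argument fully
# determines the output without clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# modal value of an integer vector; ties broken toward smallest |value|
modal_int <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  cand[which.min(abs(cand))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
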