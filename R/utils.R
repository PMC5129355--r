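`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a local RNG state: the caller's .Random.seed is
# restored afterwards, so no stochastic operation leaks global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

symmetrize <- function(m) (m + t(m)) / 2

stop_ <- function(...) stop(..., call. = FALSE)
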