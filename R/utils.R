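# internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so simulators compose without clobbering it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed, stable and < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
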