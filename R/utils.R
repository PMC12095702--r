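# Run an expression under a temporary RNG seed, restoring the caller's
# random state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fixed-offset sub-seed derivation so that independent random components
# (event times, noise, replicate draws) each get their own stream from one
# user-facing seed. Offsets are arbitrary large coprime constants; results
# stay below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) + 999983 * stream) %% 2147483647
}
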