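# Internal helpers shared across modules.

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL/NA means "use the current RNG state".
.withSeed <- function(seed, expr) {
  if (is.null(seed) || length(seed) == 0L || is.na(seed))
    return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Coerce a Recording or matrix to a channels x samples matrix.
.asSignal <- function(x) {
  if (is(x, "Recording")) x@data
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, nrow = 1L)
  else stop("expected a Recording or a channels x samples matrix")
}

# Derive a stream of distinct sub-seeds from one base seed (kept < 2^31).
.subSeeds <- function(seed, n) {
  if (is.null(seed) || is.na(seed)) return(rep(NA_real_, n))
  (as.numeric(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483647
}
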