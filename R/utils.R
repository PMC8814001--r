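# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators are pure functions of their
# configs.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a distinct 31-bit sub-seed from a base seed, so independent draws
# inside one run do not reuse a stream.
subSeed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483647L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# TRUE where x is NA or empty string: AIRR encodes absent calls both ways.
isAbsent <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
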