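## Internal helpers.

## Evaluate expr with a local RNG stream seeded at `seed`, restoring the
## caller's .Random.seed afterwards so package functions never clobber global
## reproducibility. All stochastic entry points funnel through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a deterministic sub-seed (< 2^31) from a master seed and a stream
## label, so independent stages never share a stream.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

stopIf <- function(cond, msg, ...) if (cond) stop(sprintf(msg, ...), call. = FALSE)

## Signed binary check for choice codes.
assertChoices <- function(x) {
  stopIf(!all(x %in% c(-1, 1)), "choices must be coded -1 (left) / +1 (right)")
  invisible(x)
}
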