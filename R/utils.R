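# evaluate expr with a locally-set RNG seed, restoring the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seed from a global seed, kept inside 32-bit range
child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero to `digits` decimals (tabulation convention;
# base round() is round-half-even)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
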