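# Internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit signed integer range (R integers are 32-bit).
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(stream)) %% 2147483587)
}

# Code a label vector as a factor in first-appearance order.
firstAppearanceFactor <- function(x) {
  x <- as.character(x)
  factor(x, levels = unique(x))
}
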