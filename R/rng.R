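#' Derive a child seed from a root seed and a stage key
#'
#' All stochastic operations in the package draw their randomness from a
#' stream seeded by `child_seed(root, key)`, where `key` is a short string
#' naming the stage (e.g. `"sources"`, `"reads"`, `"trait"`). This makes
#' every stage independently reproducible from the single root seed: rerunning
#' one stage never perturbs the draws of another.
#'
#' The derivation is a plain polynomial string hash of `key` folded into the
#' root seed, reduced modulo 2^31 - 1 so the result is always a valid R
#' integer seed.
#'
#' @param root integer root seed.
#' @param key character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(key))
  m <- 2147483647
  h <- as.double(root) %% m
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% m
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded by seed; restores state after.
with_child_seed <- function(root, key, expr) {
  withr::with_seed(child_seed(root, key), expr)
}
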