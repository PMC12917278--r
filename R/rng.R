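# Seed management: every stochastic stage draws from a named substream derived
# from one master seed, so changing one stage (e.g. the model fit) does not
# perturb the others.

#' Derive a deterministic sub-seed from a master seed and a stream label
#'
#' Hashes the label into the 31-bit integer range and mixes it with the master
#' seed. Used so that the component centers, covariances, point draws, true
#' function, model fit and train/test split of one trial each consume an
#' independent, reproducible stream.
#'
#' @param seed Integer master seed.
#' @param label Character stream name, e.g. `"points_source"`.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483629  # largest prime below 2^31
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(((abs(seed) %% m) * 7919 + h) %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
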