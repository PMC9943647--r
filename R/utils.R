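# Run expr under a given seed, restoring the caller's RNG state afterwards:
# all stochastic paths in the package flow through this, so nothing draws
# from global entropy.
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop_bindpoly("seed is mandatory", "bindpoly_invalid_input")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Dirichlet draw with mean `mean` (a probability vector) and concentration
# `alpha` via normalised gamma variates; alpha = 0 returns the mean exactly
# (noiseless mode). Components with zero mean stay exactly zero.
rdirichlet_mean <- function(mean, alpha) {
  if (alpha == 0) return(mean)
  g <- stats::rgamma(length(mean), shape = alpha * mean, rate = 1)
  if (sum(g) == 0) return(mean)
  g / sum(g)
}
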