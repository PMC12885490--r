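# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive n reproducible sub-seeds from one master seed (all < 2^31).
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
.elu_grad <- function(x) {
  g <- array(1, dim(x) %||% length(x))
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g
}

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
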