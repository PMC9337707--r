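# Internal helpers: classed error conditions, seed scoping, numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Input errors (bad arguments, malformed files) vs validation errors
# (well-formed input violating a model invariant) vs numerical failures.
# The CLI maps these onto distinct exit codes.
fm_stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("fm_input_error", "fm_error", "error", "condition")))
}

fm_stop_validation <- function(msg) {
  stop(errorCondition(msg,
    class = c("fm_validation_error", "fm_input_error", "fm_error", "error", "condition")))
}

fm_stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("fm_numerical_error", "fm_error", "error", "condition")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. seed = NULL means "use the ambient RNG".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Normalized weights from log-weights, stable for |x| up to ~1e4.
softmax <- function(x) {
  m <- max(x)
  w <- exp(x - m)
  w / sum(w)
}

is_symmetric_tol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

check_scalar_count <- function(n, what = "n") {
  if (is.null(n) || length(n) != 1L || !is.finite(n) || n < 1)
    fm_stop_input(sprintf("%s must be a single value >= 1", what))
  n
}
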