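#' Regularize an LD matrix toward the identity
#'
#' Convex combination `R_lam = (1 - lam) R0 + lam I`. The diagonal stays
#' exactly 1, symmetry is preserved, and every eigenvalue is shifted as
#' `(1 - lam) e + lam`, so the smallest eigenvalue increases whenever the
#' input is not already the identity.
#'
#' @param R0 LD matrix (square, symmetric, unit diagonal).
#' @param lam Regularization level in `[0, 1]`.
#' @return The regularized matrix, with attribute `lam`.
#' @export
regularize_ld <- function(R0, lam) {
  if (length(lam) != 1L || !is.finite(lam) || lam < 0 || lam > 1)
    fm_stop_input("lam must lie in [0, 1]")
  if (!is.matrix(R0) || nrow(R0) != ncol(R0))
    fm_stop_input("R0 must be a square matrix")
  R <- (1 - lam) * R0 + lam * diag(nrow(R0))
  diag(R) <- 1
  attr(R, "lam") <- lam
  attr(R, "source") <- attr(R0, "source")
  R
}

# Null log-likelihood of z under N(0, (1-lam) R0 + lam I), via the
# eigendecomposition R0 = U diag(e) U': with w = U'z the objective is
# -0.5 * sum[ log((1-lam) e_i + lam) + w_i^2 / ((1-lam) e_i + lam) ]
# (dropping the dimension-constant -J/2 log(2 pi), which does not depend
# on lam).
lambda_objective <- function(lam, evalues, w2) {
  s <- (1 - lam) * evalues + lam
  if (any(s <= 0)) return(-Inf)
  -0.5 * sum(log(s) + w2 / s)
}

#' Maximum-likelihood LD regularization level
#'
#' Estimates `lambda` by maximizing the multivariate normal null
#' likelihood of the (PVE-adjusted) z-scores,
#' `N(z_adj; 0, (1 - lambda) R0 + lambda I)`, over `lambda` in `[0, 1]`.
#' When the z-scores and LD matrix are mutually consistent the estimate is
#' close to zero; gross inconsistency pushes it toward one.
#'
#' One eigendecomposition of `R0` reduces each objective evaluation to
#' O(J). Negative eigenvalues of a non-positive-definite `R0` are allowed,
#' but the search range is restricted so that every shifted eigenvalue
#' stays above 1e-10 (otherwise the likelihood may be unbounded). If the
#' objective is flat -- e.g. `R0 = I`, where the combination is the
#' identity for every `lambda` -- the smallest maximizing value (0) is
#' returned.
#'
#' @param z_adj (PVE-adjusted) z-scores; raw z-scores are acceptable when
#'   the sample size is unknown and effects are small.
#' @param R0 LD matrix from the reference panel.
#' @return The estimated `lambda` in `[0, 1]`, with the attained null
#'   log-likelihood (up to the lam-free constant) as attribute
#'   `"loglik"`.
#' @export
estimate_lambda <- function(z_adj, R0) {
  J <- nrow(R0)
  if (length(z_adj) != J) fm_stop_input("length(z_adj) must match dim(R0)")
  if (!is_symmetric_tol(R0)) fm_stop_validation("R0 must be symmetric")
  eg <- eigen((R0 + t(R0)) / 2, symmetric = TRUE)
  w2 <- drop(crossprod(eg$vectors, z_adj))^2
  emin <- min(eg$values)

  # Keep every shifted eigenvalue above 1e-10: for emin < 1 this requires
  # lam > (1e-10 - emin) / (1 - emin).
  lo <- if (emin >= 1e-10) 0 else min(1, (1e-10 - emin) / (1 - emin) + 1e-12)
  f <- function(lam) lambda_objective(lam, eg$values, w2)
  if (!any(is.finite(vapply(c(lo, (lo + 1) / 2, 1), f, numeric(1)))))
    fm_stop_numerical("null log-likelihood is non-finite over the whole lambda interval")

  opt <- stats::optimize(f, interval = c(lo, 1), maximum = TRUE, tol = 1e-7)
  lam <- opt$maximum
  # Prefer the smallest maximizing value when the objective is flat.
  if (lo == 0 && f(0) >= opt$objective - 1e-9) lam <- 0
  attr(lam, "loglik") <- f(lam)
  lam
}
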