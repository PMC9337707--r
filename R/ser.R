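#' Single effect regression (SER) from sufficient statistics
#'
#' Fits the Bayesian single effect regression -- the multiple regression
#' model with exactly one nonzero coefficient and a `N(0, prior_var)` slab
#' on that coefficient -- given per-SNP sufficient quantities: `xtr = X'r`
#' for the current residual target `r`, and `d = diag(X'X)`. The posterior
#' is available in closed form: per SNP, the least-squares estimate
#' `bhat_j = xtr_j / d_j` has sampling variance `s2_j = sigma2 / d_j`, a
#' normal-means Bayes factor compares the slab against the null, and the
#' posterior assignment probabilities are the prior-weighted normalized
#' Bayes factors.
#'
#' The SER posterior depends on the data only through the pairs
#' `(xtr_j, d_j)`; it never uses off-diagonal LD. SNPs with `d_j = 0`
#' (monomorphic after centering) get Bayes factor 1 and zero posterior
#' moments.
#'
#' @param xtr J-vector `X'r`.
#' @param d J-vector `diag(X'X)`, non-negative.
#' @param sigma2 Residual variance, positive.
#' @param prior_var Prior effect variance `sigma0^2 >= 0`.
#' @param prior_weights Prior assignment probabilities; default uniform.
#'   Zero weights exclude SNPs from assignment.
#' @return An object of class `"ser_fit"`: list with `alpha` (posterior
#'   assignment probabilities, summing to 1), `mu1`/`mu2` (conditional
#'   posterior first/second moments of the effect given assignment),
#'   `lbf` (per-SNP log Bayes factors), `lbf_model` (log Bayes factor of
#'   the whole SER against the null), and `prior_var`.
#' @export
fit_ser <- function(xtr, d, sigma2, prior_var, prior_weights = NULL) {
  J <- length(xtr)
  if (length(d) != J) fm_stop_input("xtr and d must have the same length")
  if (any(d < 0)) fm_stop_input("d must be non-negative")
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0)
    fm_stop_input("sigma2 must be a positive scalar")
  if (length(prior_var) != 1L || !is.finite(prior_var) || prior_var < 0)
    fm_stop_input("prior_var must be a non-negative scalar")
  pw <- prior_weights %||% rep(1 / J, J)
  if (length(pw) != J || any(pw < 0) || sum(pw) <= 0)
    fm_stop_input("prior_weights must be non-negative and sum to a positive value")
  pw <- pw / sum(pw)

  lbf <- numeric(J)
  mu1 <- numeric(J)
  post_var <- numeric(J)
  pos <- d > 0
  if (prior_var > 0 && any(pos)) {
    s2 <- sigma2 / d[pos]                  # sampling variance of bhat
    bhat <- xtr[pos] / d[pos]
    lbf[pos] <- 0.5 * log(s2 / (s2 + prior_var)) +
      0.5 * (bhat^2 / s2) * prior_var / (prior_var + s2)
    post_var[pos] <- 1 / (1 / prior_var + d[pos] / sigma2)
    mu1[pos] <- post_var[pos] * xtr[pos] / sigma2
  }
  lw <- ifelse(pw > 0, log(pw), -Inf) + lbf
  alpha <- softmax(lw)
  list2 <- list(alpha = alpha, mu1 = mu1, mu2 = post_var + mu1^2, lbf = lbf,
                lbf_model = logsumexp(lw), prior_var = prior_var)
  class(list2) <- "ser_fit"
  list2
}

# Log Bayes factor of the SER at a given prior variance; the empirical
# Bayes objective maximized by estimate_prior_variance().
ser_lbf_model <- function(prior_var, xtr, d, sigma2, pw) {
  J <- length(xtr)
  lbf <- numeric(J)
  pos <- d > 0
  if (prior_var > 0 && any(pos)) {
    s2 <- sigma2 / d[pos]
    bhat <- xtr[pos] / d[pos]
    lbf[pos] <- 0.5 * log(s2 / (s2 + prior_var)) +
      0.5 * (bhat^2 / s2) * prior_var / (prior_var + s2)
  }
  logsumexp(ifelse(pw > 0, log(pw), -Inf) + lbf)
}

#' Empirical Bayes estimate of the SER prior effect variance
#'
#' Maximizes the SER marginal log-likelihood (equivalently its log Bayes
#' factor against the null) over the prior variance `sigma0^2`, searched on
#' the log scale over `bounds`, with an explicit boundary comparison at
#' `sigma0^2 = 0`: if no positive value beats the null, the effect is
#' pruned and 0 is returned.
#'
#' @inheritParams fit_ser
#' @param method `"optimize"` (bounded 1-D search on the log scale, the
#'   default) or `"em"` (fixed-point iteration of the posterior
#'   second-moment update).
#' @param bounds Length-2 positive numeric search interval for
#'   `sigma0^2`.
#' @return The fitted prior variance (scalar, `>= 0`).
#' @export
estimate_prior_variance <- function(xtr, d, sigma2, prior_weights = NULL,
                                    method = c("optimize", "em"),
                                    bounds = c(1e-10, 1e3)) {
  method <- match.arg(method)
  J <- length(xtr)
  pw <- prior_weights %||% rep(1 / J, J)
  pw <- pw / sum(pw)
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2])
    fm_stop_input("bounds must be an increasing pair of positive values")

  if (method == "optimize") {
    negll <- function(lv) -ser_lbf_model(exp(lv), xtr, d, sigma2, pw)
    opt <- stats::optimize(negll, interval = log(bounds), tol = 1e-8)
    v <- exp(opt$minimum)
  } else {
    # EM: v <- sum_j alpha_j * E[b^2 | gamma = j], iterated to a fixed point.
    v <- max(sum((xtr / pmax(d, 1))^2 * (d > 0)) / max(1, sum(d > 0)), bounds[1])
    for (it in seq_len(100)) {
      fit <- fit_ser(xtr, d, sigma2, v, pw)
      vnew <- sum(fit$alpha * fit$mu2)
      if (!is.finite(vnew) || vnew < bounds[1]) vnew <- 0
      if (abs(vnew - v) < 1e-10 * max(1, v)) { v <- vnew; break }
      v <- vnew
      if (v == 0) break
    }
  }
  # Boundary check: the null model has log Bayes factor 0 by definition.
  if (v <= 0 || ser_lbf_model(v, xtr, d, sigma2, pw) <= 0) 0 else v
}
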