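#' Fit the sum of single effects model from sufficient statistics (IBSS-ss)
#'
#' Fits the SuSiE model `b = b_1 + ... + b_L`, each `b_l` a single effect
#' vector with exactly one nonzero coordinate, by iterative Bayesian
#' stepwise selection on sufficient statistics. Each sweep visits the
#' effects `l = 1..L` in order, forms the residual target
#' `X'r_l = X'y - X'X (sum_{k != l} bbar_k)` using only `X'X` (never `X`),
#' and refits effect `l` as a single effect regression, re-estimating its
#' prior variance by empirical Bayes when requested. The per-iteration cost
#' is O(J^2), independent of the sample size.
#'
#' The algorithm is coordinate ascent on the evidence lower bound (ELBO);
#' the recorded ELBO trace is non-decreasing and convergence is declared
#' when the increase over one sweep falls below `tol`.
#'
#' Two data regimes are supported via `mode`. With `"sufficient"` the
#' statistics are exact (individual-level data or in-sample LD) and the
#' residual variance is estimated each sweep, so the fit is identical to
#' running the individual-level algorithm on `X, y`. With `"summary"` the
#' LD matrix comes from a reference panel; the residual variance is then
#' fixed at `yty/n` (1 for standardized data) because estimating it from
#' approximate statistics is unreliable.
#'
#' @param ss A [suff_stats()] object.
#' @param L Maximum number of single effects (default 10).
#' @param mode `"sufficient"` (estimate `sigma2`) or `"summary"` (fix
#'   `sigma2 = yty/n`). Overridden by `fix_sigma2` if supplied.
#' @param fix_sigma2 Logical; fix the residual variance instead of
#'   estimating it. Default follows `mode`.
#' @param sigma2_init Initial (or fixed) residual variance; default
#'   `yty/n`.
#' @param max_iter Maximum number of sweeps (default 100).
#' @param tol Convergence tolerance on the ELBO increase (default 1e-3).
#' @param prior_weights Prior assignment probabilities over SNPs, shared by
#'   all effects; default uniform. Zero entries exclude SNPs.
#' @param estimate_prior_variance Re-estimate each effect's prior variance
#'   at every update (default `TRUE`); effects whose estimate hits the
#'   boundary 0 are inactive but revisitable.
#' @param scaled_prior_variance Prior effect variance as a fraction of
#'   `yty/n`, used to initialize (and, when `estimate_prior_variance =
#'   FALSE`, fix) the prior variances. Default 0.2.
#' @param s_init Optional warm start: a list (or `susie_fit`) with
#'   `alpha`, `mu1`, `mu2`, `prior_vars` and optionally `sigma2`.
#'
#' @return An object of class `"susie_fit"`: `alpha`, `mu1`, `mu2`
#'   (L x J), `prior_vars` (L), `sigma2`, `elbo` (per-sweep trace),
#'   `niter`, `converged`, `pip` (J), `lbf_per_effect` (L), `snp`, and the
#'   `settings` used (for refitting).
#' @seealso [fit_susie_rss()], [refine_fit()], [collect_credible_sets()]
#' @export
fit_susie_ss <- function(ss, L = 10,
                         mode = c("sufficient", "summary"),
                         fix_sigma2 = NULL, sigma2_init = NULL,
                         max_iter = 100, tol = 1e-3,
                         prior_weights = NULL,
                         estimate_prior_variance = TRUE,
                         scaled_prior_variance = 0.2,
                         s_init = NULL) {
  if (!inherits(ss, "suff_stats")) fm_stop_input("ss must be a suff_stats object")
  mode <- match.arg(mode)
  J <- ss$J
  if (length(L) != 1L || L < 1) fm_stop_input("L must be a positive integer")
  L <- as.integer(min(L, J))
  if (tol <= 0) fm_stop_input("tol must be positive")
  fix_sigma2 <- fix_sigma2 %||% (mode == "summary")

  pw <- prior_weights %||% rep(1 / J, J)
  if (length(pw) != J || any(pw < 0) || sum(pw) <= 0)
    fm_stop_input("prior_weights must be non-negative with a positive sum")
  pw <- pw / sum(pw)

  vscale <- ss$yty / ss$n
  vbounds <- c(1e-10, 1e3) * vscale
  sigma2 <- sigma2_init %||% vscale
  if (sigma2 <= 0) fm_stop_input("sigma2_init must be positive")

  if (!is.null(s_init)) {
    alpha <- s_init$alpha; mu1 <- s_init$mu1; mu2 <- s_init$mu2
    prior_vars <- s_init$prior_vars
    if (is.null(alpha) || !all(dim(alpha) == c(L, J)) ||
        !all(dim(mu1) == c(L, J)) || !all(dim(mu2) == c(L, J)) ||
        length(prior_vars) != L)
      fm_stop_input("s_init dimensions do not match L and J")
    if (!is.null(s_init$sigma2) && !fix_sigma2) sigma2 <- s_init$sigma2
  } else {
    alpha <- matrix(1 / J, L, J)
    mu1 <- matrix(0, L, J)
    mu2 <- matrix(0, L, J)
    prior_vars <- rep(scaled_prior_variance * vscale, L)
  }

  d <- diag(ss$XtX)
  lbf_eff <- numeric(L)
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  niter <- 0L

  for (iter in seq_len(max_iter)) {
    bbar <- colSums(alpha * mu1)
    for (l in seq_len(L)) {
      bl <- alpha[l, ] * mu1[l, ]
      xtr <- ss$Xty - drop(ss$XtX %*% (bbar - bl))
      if (estimate_prior_variance)
        prior_vars[l] <- estimate_prior_variance(xtr, d, sigma2, pw,
                                                 bounds = vbounds)
      ser <- fit_ser(xtr, d, sigma2, prior_vars[l], pw)
      alpha[l, ] <- ser$alpha
      mu1[l, ] <- ser$mu1
      mu2[l, ] <- ser$mu2
      lbf_eff[l] <- ser$lbf_model
      bbar <- bbar - bl + alpha[l, ] * mu1[l, ]
    }
    e <- elbo_state(ss, alpha, mu1, mu2, prior_vars, pw, sigma2)
    if (!is.finite(e))
      fm_stop_numerical(sprintf("ELBO became non-finite at iteration %d", iter))
    elbo_trace <- c(elbo_trace, e)
    niter <- iter
    if (iter > 1 && e - elbo_prev < tol) { converged <- TRUE; break }
    elbo_prev <- e
    # sigma2 is updated after the convergence check so the recorded trace
    # is evaluated at the sigma2 in force during the sweep.
    if (!fix_sigma2) sigma2 <- sigma2_from_state(ss, alpha, mu1, mu2)
  }

  fit <- structure(list(
    alpha = alpha, mu1 = mu1, mu2 = mu2, prior_vars = prior_vars,
    sigma2 = sigma2, elbo = elbo_trace, niter = niter,
    converged = converged, lbf_per_effect = lbf_eff,
    snp = ss$snp, J = J, L = L,
    settings = list(L = L, mode = mode, fix_sigma2 = fix_sigma2,
                    sigma2_init = sigma2_init, max_iter = max_iter,
                    tol = tol, prior_weights = pw,
                    estimate_prior_variance = estimate_prior_variance,
                    scaled_prior_variance = scaled_prior_variance)),
    class = "susie_fit")
  fit$pip <- compute_pips(fit)
  fit
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf(
    "susie_fit: J = %d SNPs, L = %d effects (%d non-null), sigma2 = %.4g\n",
    x$J, x$L, sum(x$prior_vars > 0), x$sigma2))
  cat(sprintf("  ELBO = %.4f after %d iteration(s)%s\n",
              utils::tail(x$elbo, 1), x$niter,
              if (x$converged) " (converged)" else " (not converged)"))
  invisible(x)
}

# Posterior-expected residual sum of squares E || y - X b ||^2 under the
# variational posterior, computed from sufficient statistics only:
#   yty - 2 bbar' Xty + bbar' XtX bbar
#       + sum_l [ sum_j d_j alpha_lj mu2_lj - bbar_l' XtX bbar_l ]
erss_state <- function(ss, alpha, mu1, mu2) {
  B <- alpha * mu1                     # row l = posterior mean of b_l
  bbar <- colSums(B)
  quad <- sum(bbar * drop(ss$XtX %*% bbar))
  cross <- sum(vapply(seq_len(nrow(B)), function(l) {
    v <- B[l, ]
    sum(v * drop(ss$XtX %*% v))
  }, numeric(1)))
  varsum <- sum(colSums(alpha * mu2) * diag(ss$XtX))
  ss$yty - 2 * sum(bbar * ss$Xty) + quad - cross + varsum
}

sigma2_from_state <- function(ss, alpha, mu1, mu2) {
  erss <- erss_state(ss, alpha, mu1, mu2)
  floor_ <- 1e-8 * ss$yty
  if (erss <= floor_) {
    warning("expected residual sum of squares is non-positive (inconsistent ",
            "summary data?); residual variance clamped at its floor")
    erss <- floor_
  }
  erss / ss$n
}

# KL( q(b_l) || p(b_l) ) for one effect, depending only on the variational
# state: categorical part sum_j alpha_j log(alpha_j / pi_j) plus the
# conditional Gaussian KL for each assignment. Point-mass components
# (zero conditional variance, e.g. monomorphic SNPs) contribute only the
# categorical part.
effect_kl <- function(a, m1, m2, v0, pw) {
  pos <- a > 0 & pw > 0
  kl <- sum(a[pos] * log(a[pos] / pw[pos]))
  if (v0 > 0) {
    v <- pmax(m2 - m1^2, 0)
    g <- pos & v > 0
    if (any(g))
      kl <- kl + sum(a[g] * (0.5 * (log(v0 / v[g]) + (v[g] + m1[g]^2) / v0 - 1)))
  }
  kl
}

elbo_state <- function(ss, alpha, mu1, mu2, prior_vars, pw, sigma2) {
  erss <- erss_state(ss, alpha, mu1, mu2)
  kl <- sum(vapply(seq_len(nrow(alpha)), function(l) {
    effect_kl(alpha[l, ], mu1[l, ], mu2[l, ], prior_vars[l], pw)
  }, numeric(1)))
  -0.5 * ss$n * log(2 * pi * sigma2) - erss / (2 * sigma2) - kl
}

#' Evidence lower bound of a fitted model
#'
#' Recomputes the variational objective from the fitted state and the
#' sufficient statistics: the expected Gaussian log-likelihood under the
#' posterior (a function of `yty`, `Xty`, `XtX` and the posterior first and
#' second moments) minus the KL divergences of the L single-effect
#' posteriors from their priors. The last element of `fit$elbo` equals this
#' value.
#'
#' @param fit A `susie_fit`.
#' @param ss The [suff_stats()] the model was fitted to.
#' @return Scalar ELBO.
#' @export
susie_elbo <- function(fit, ss) {
  if (fit$J != ss$J) fm_stop_input("fit and ss dimensions differ")
  elbo_state(ss, fit$alpha, fit$mu1, fit$mu2, fit$prior_vars,
             fit$settings$prior_weights, fit$sigma2)
}

#' Residual variance estimate from a fitted model
#'
#' Returns `ERSS / n`, the posterior-expected residual sum of squares
#' divided by the sample size. Non-positive ERSS (possible when
#' approximate summary statistics are mutually inconsistent) is clamped at
#' `1e-8 * yty` with a warning.
#'
#' @inheritParams susie_elbo
#' @return Scalar residual variance estimate.
#' @export
estimate_sigma2 <- function(fit, ss) {
  if (fit$J != ss$J) fm_stop_input("fit and ss dimensions differ")
  sigma2_from_state(ss, fit$alpha, fit$mu1, fit$mu2)
}

#' Posterior inclusion probabilities
#'
#' `PIP_j = 1 - prod_l (1 - alpha_lj)`, the posterior probability that SNP
#' j has a nonzero effect, taking the product over effects. Effects whose
#' estimated prior variance is 0 carry no signal (their assignment
#' probabilities are prior-level noise) and are excluded when
#' `prune_null_effects` is set.
#'
#' @param fit A `susie_fit`, or a plain L x J matrix of assignment
#'   probabilities (no pruning information in that case).
#' @param prune_null_effects Exclude effects with `prior_var = 0`
#'   (default `TRUE`; only applies to `susie_fit` input).
#' @return J-vector of PIPs in `[0, 1]`.
#' @export
compute_pips <- function(fit, prune_null_effects = TRUE) {
  if (inherits(fit, "susie_fit")) {
    alpha <- fit$alpha
    if (prune_null_effects) alpha <- alpha[fit$prior_vars > 0, , drop = FALSE]
  } else if (is.matrix(fit)) {
    alpha <- fit
  } else {
    fm_stop_input("fit must be a susie_fit or an L x J matrix")
  }
  if (nrow(alpha) == 0) return(numeric(ncol(fit$alpha %||% fit)))
  pmin(pmax(1 - apply(1 - alpha, 2, prod), 0), 1)
}

#' Fine-map from z-scores (or effect estimates) and an LD matrix
#'
#' Convenience front end composing the summary-data workflow: convert
#' effect estimates to z-scores if needed, apply the PVE adjustment when
#' the sample size is known, build sufficient statistics, optionally
#' regularize the LD matrix, fit by IBSS-ss, and optionally refine the fit.
#'
#' When `n` is supplied the exact standardized-data identities are used
#' (`X'X = nR`, `X'y = sqrt(n) z_adj`, `y'y = n`). When `n` is unknown the
#' raw z-scores stand in for the adjusted ones and the fit uses
#' `X'X = R`, `X'y = z` with unit phenotypic variance and `sigma2 = 1`;
#' this is a good approximation when all effects are small.
#'
#' @param z z-scores (or `NULL` if `bhat`/`shat` given).
#' @param R LD matrix (J x J correlation matrix).
#' @param n Study sample size, or `NULL` if unknown.
#' @param bhat,shat Marginal effects and standard errors (alternative to
#'   `z`).
#' @param lam LD regularization: `"none"`, `"estimate"` (maximum
#'   likelihood, see [estimate_lambda()]), or a numeric value in `[0, 1]`.
#' @param refine Run the ELBO-guided refinement ([refine_fit()]) after the
#'   initial fit (default `TRUE`).
#' @param mode Data regime passed to [fit_susie_ss()]; default
#'   `"summary"` (fixed residual variance), appropriate for
#'   reference-panel LD.
#' @param ... Further arguments to [fit_susie_ss()].
#' @return A `susie_fit` (see [fit_susie_ss()]), with the regularization
#'   level used stored as `$lam`.
#' @export
#' @examples
#' # Two SNPs in complete LD in the reference panel, z-scores 6 and 7:
#' fit <- fit_susie_rss(z = c(6, 7), R = matrix(1, 2, 2), refine = FALSE)
#' round(fit$pip, 4)
fit_susie_rss <- function(z = NULL, R, n = NULL, bhat = NULL, shat = NULL,
                          lam = "none", refine = TRUE,
                          mode = c("summary", "sufficient"), ...) {
  mode <- match.arg(mode)
  if (is.null(z)) {
    if (is.null(bhat) || is.null(shat))
      fm_stop_input("provide z, or bhat and shat")
    z <- zscores_from_effects(summary_data(bhat = bhat, shat = shat))
  }
  if (length(z) != nrow(R))
    fm_stop_input("length(z) must match the dimension of R")

  z_adj <- if (is.null(n)) pve_adjusted_z(z, NULL) else pve_adjusted_z(z, n)
  lam_used <- 0
  if (identical(lam, "estimate")) {
    lam_used <- estimate_lambda(z_adj, R)
    R <- regularize_ld(R, lam_used)
  } else if (is.numeric(lam)) {
    lam_used <- lam
    R <- regularize_ld(R, lam_used)
  } else if (!identical(lam, "none")) {
    fm_stop_input("lam must be \"none\", \"estimate\", or a value in [0, 1]")
  }

  ss <- if (is.null(n)) {
    # Unknown n: unit-phenotype-variance convention, sigma2 = yty/n = 1.
    suff_stats(XtX = R, Xty = z, yty = 2, n = 2)
  } else {
    suff_from_standardized_summary(z_adj, R, n)
  }
  fit <- fit_susie_ss(ss, mode = mode, ...)
  if (refine) fit <- refine_fit(fit, ss, R)
  fit$lam <- lam_used
  fit
}
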