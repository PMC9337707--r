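# Independent reference implementations used as oracles. These work from
# first principles (explicit densities, individual-level residuals,
# delete-one solves, grid searches) and share no code with the package
# internals they check.

# Brute-force SER posterior over the J discrete assignments: directly
# evaluates the prior-weighted marginal density of bhat_j under slab and
# null using dnorm, and normalizes.
oracle_ser_alpha <- function(xtr, d, sigma2, v0, pw = NULL) {
  J <- length(xtr)
  if (is.null(pw)) pw <- rep(1 / J, J)
  bhat <- xtr / d
  s2 <- sigma2 / d
  bf <- stats::dnorm(bhat, 0, sqrt(s2 + v0)) / stats::dnorm(bhat, 0, sqrt(s2))
  w <- pw * bf
  w / sum(w)
}

# SER marginal log-likelihood ratio against the null, via dnorm.
oracle_ser_loglik <- function(v0, bhat, s2, pw) {
  lbf <- stats::dnorm(bhat, 0, sqrt(s2 + v0), log = TRUE) -
    stats::dnorm(bhat, 0, sqrt(s2), log = TRUE)
  m <- max(lbf + log(pw))
  m + log(sum(exp(lbf + log(pw) - m)))
}

# From-scratch IBSS on individual-level data (X, y): per-SNP statistics
# are recomputed from explicit residual vectors in R^n at every update,
# never from X'X. Matches the package's sufficient-statistic fitter by
# the likelihood-equivalence of the two data representations.
oracle_ibss <- function(X, y, L = 10, tol = 1e-3, max_iter = 100,
                        standardize = TRUE, estimate_sigma2 = TRUE) {
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- y - mean(y)
  n <- nrow(X)
  if (standardize) {
    X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
    y <- y / sqrt(mean(y^2))
  }
  J <- ncol(X)
  L <- min(L, J)
  yty <- sum(y^2)
  d <- colSums(X^2)
  pw <- rep(1 / J, J)
  vb <- log(c(1e-10, 1e3) * yty / n)

  alpha <- matrix(1 / J, L, J)
  mu1 <- matrix(0, L, J)
  mu2 <- matrix(0, L, J)
  v <- rep(0.2 * yty / n, L)
  sigma2 <- yty / n
  elbo_prev <- -Inf
  elbo_trace <- numeric(0)

  fitted <- drop(X %*% colSums(alpha * mu1))
  for (iter in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      fitted_l <- drop(X %*% (alpha[l, ] * mu1[l, ]))
      r <- y - (fitted - fitted_l)           # residual vector in R^n
      bhat <- drop(crossprod(X, r)) / d
      s2 <- sigma2 / d
      opt <- stats::optimize(function(lv)
        -oracle_ser_loglik(exp(lv), bhat, s2, pw), interval = vb, tol = 1e-8)
      vl <- exp(opt$minimum)
      if (oracle_ser_loglik(vl, bhat, s2, pw) <= 0) vl <- 0
      v[l] <- vl
      if (vl > 0) {
        lbf <- stats::dnorm(bhat, 0, sqrt(s2 + vl), log = TRUE) -
          stats::dnorm(bhat, 0, sqrt(s2), log = TRUE)
        w <- exp(lbf + log(pw) - max(lbf + log(pw)))
        alpha[l, ] <- w / sum(w)
        pv <- 1 / (1 / vl + d / sigma2)
        mu1[l, ] <- pv * d * bhat / sigma2
        mu2[l, ] <- pv + mu1[l, ]^2
      } else {
        alpha[l, ] <- pw
        mu1[l, ] <- 0
        mu2[l, ] <- 0
      }
      fitted <- fitted - fitted_l + drop(X %*% (alpha[l, ] * mu1[l, ]))
    }
    # ELBO: expected residual sum of squares via explicit fitted values.
    erss <- sum((y - fitted)^2) +
      sum(vapply(seq_len(L), function(l) {
        bl <- alpha[l, ] * mu1[l, ]
        sum(d * alpha[l, ] * mu2[l, ]) - sum(drop(X %*% bl)^2)
      }, numeric(1)))
    kl <- sum(vapply(seq_len(L), function(l) {
      a <- alpha[l, ]
      k <- sum(a * log(a / pw))
      if (v[l] > 0) {
        pv <- pmax(mu2[l, ] - mu1[l, ]^2, 0)
        g <- pv > 0
        k <- k + sum(a[g] * 0.5 * (log(v[l] / pv[g]) +
                                     (pv[g] + mu1[l, g]^2) / v[l] - 1))
      }
      k
    }, numeric(1)))
    e <- -0.5 * n * log(2 * pi * sigma2) - erss / (2 * sigma2) - kl
    elbo_trace <- c(elbo_trace, e)
    if (iter > 1 && e - elbo_prev < tol) break
    elbo_prev <- e
    if (estimate_sigma2) sigma2 <- erss / n
  }
  pip_rows <- alpha[v > 0, , drop = FALSE]
  pip <- if (nrow(pip_rows) == 0) numeric(J) else 1 - apply(1 - pip_rows, 2, prod)
  list(alpha = alpha, mu1 = mu1, v = v, sigma2 = sigma2, pip = pip,
       elbo = elbo_trace)
}

# Delete-one conditional of a multivariate normal N(0, S): mean and
# variance of coordinate j given the rest, via an explicit
# (J-1) x (J-1) solve.
oracle_delete_one <- function(z, S, j) {
  Sjj <- S[-j, -j, drop = FALSE]
  s <- S[j, -j]
  w <- solve(Sjj, z[-j])
  list(mean = sum(s * w),
       var = S[j, j] - sum(s * solve(Sjj, s)))
}
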