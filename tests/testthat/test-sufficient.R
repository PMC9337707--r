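# Construction and validation of summary data and sufficient statistics.

test_that("z-scores are the elementwise quotient bhat / shat", {
  expect_equal(zscores_from_effects(summary_data(bhat = 1, shat = 0.5)), 2)
  expect_equal(zscores_from_effects(summary_data(bhat = c(0, 0), shat = c(1, 2))),
               c(0, 0))
  expect_equal(
    zscores_from_effects(summary_data(bhat = c(0.3, -0.4), shat = c(0.1, 0.2))),
    c(3, -2))
})

test_that("summary data validation rejects bad inputs and names the SNP", {
  expect_error(summary_data(bhat = c(1, 2)), class = "fm_input_error")
  err <- expect_error(
    summary_data(snp = c("rs1", "rs2"), bhat = c(1, 2), shat = c(0.1, -1)),
    class = "fm_validation_error")
  expect_match(conditionMessage(err), "rs2")
  expect_error(summary_data(bhat = c(1, 2), shat = 0.5), class = "fm_input_error")
  expect_error(summary_data(bhat = 1, shat = 0.5, z = 5),
               class = "fm_validation_error")
  expect_error(zscores_from_effects(summary_data(z = c(1, 2))),
               class = "fm_input_error")
})

test_that("PVE adjustment shrinks z-scores toward zero, preserving sign", {
  expect_equal(pve_adjusted_z(c(0, 0, 0), 1000), c(0, 0, 0))
  expect_equal(pve_adjusted_z(2, 4), 2 * sqrt(4 / 8))
  expect_equal(pve_adjusted_z(5, 1e9), 5, tolerance = 1e-6)
  z <- c(-8, -2, -0.5, 0, 0.5, 2, 8)
  za <- pve_adjusted_z(z, 500)
  expect_true(all(abs(za) <= abs(z)))
  expect_true(all(abs(za[z != 0]) < abs(z[z != 0])))
  expect_equal(sign(za), sign(z))
  # monotone in n toward z
  za2 <- pve_adjusted_z(z, 5000)
  expect_true(all(abs(za2) >= abs(za)))
  expect_error(pve_adjusted_z(c(1, 2), 0), class = "fm_input_error")
  expect_warning(pve_adjusted_z(c(1, 2), NULL), "sample size unknown")
})

test_that("sufficient statistics from individual data use N-denominator centering", {
  # one column equal to y: after standardization all four stats equal N
  y <- c(1, 3, 2, 6)
  X <- cbind(a = y)
  ss <- suff_from_individual(X, y, standardize = TRUE)
  expect_equal(drop(ss$XtX), 4)
  expect_equal(ss$Xty, 4)
  expect_equal(ss$yty, 4)
  expect_equal(ss$n, 4)

  # constant y: centering annihilates it
  X2 <- matrix(rnorm(20), 10, 2)
  ss2 <- suff_from_individual(X2, rep(3, 10))
  expect_equal(ss2$yty, 0)
  expect_equal(ss2$Xty, c(0, 0))

  # permuting samples leaves the statistics unchanged
  set.seed(7)
  X3 <- matrix(rnorm(60), 20, 3)
  y3 <- rnorm(20)
  p <- sample(20)
  ssa <- suff_from_individual(X3, y3)
  ssb <- suff_from_individual(X3[p, ], y3[p])
  expect_equal(ssa$XtX, ssb$XtX)
  expect_equal(ssa$Xty, ssb$Xty)
  expect_equal(ssa$yty, ssb$yty)

  err <- expect_error(
    suff_from_individual(cbind(mono = rep(2, 5), ok = rnorm(5)), rnorm(5),
                         standardize = TRUE),
    class = "fm_validation_error")
  expect_match(conditionMessage(err), "mono")
})

test_that("standardized-summary route reproduces individual-level statistics", {
  # scalar case: XtX = n, Xty = sqrt(n) * z_adj, yty = n
  ss <- suff_from_standardized_summary(3, matrix(1, 1, 1), 9)
  expect_equal(drop(ss$XtX), 9)
  expect_equal(ss$Xty, 9)
  expect_equal(ss$yty, 9)

  ss0 <- suff_from_standardized_summary(rep(0, 4), diag(4), 100)
  expect_equal(ss0$Xty, rep(0, 4))
  expect_equal(ss0$yty, 100)

  # round trip through the in-sample LD matrix is an identity
  set.seed(11)
  X <- simulate_genotypes(150, 8, list(type = "block", rho = 0.8, block_size = 4))
  y <- rnorm(150) + X[, 3]
  direct <- suff_from_individual(X, y, standardize = TRUE)
  sd <- summarize_study(X, y)
  z_adj <- pve_adjusted_z(sd$z, sd$n)
  R <- cor(X)
  via_summary <- suff_from_standardized_summary(z_adj, R, sd$n)
  expect_equal(via_summary$XtX, direct$XtX, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(via_summary$Xty, direct$Xty, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(via_summary$yty, direct$yty, tolerance = 1e-8)

  expect_error(suff_from_standardized_summary(c(1, 2), diag(3), 10),
               class = "fm_input_error")
})

test_that("effect-scale summary route recovers the generating cross-products", {
  set.seed(3)
  x <- rnorm(40)
  y <- 0.7 * x + rnorm(40)
  x <- x - mean(x); y <- y - mean(y)
  n <- 40
  xtx <- sum(x^2); xty <- sum(x * y); yty <- sum(y^2)
  bhat <- xty / xtx
  shat <- sqrt((yty - bhat^2 * xtx) / (n * xtx))
  sd <- summary_data(bhat = bhat, shat = shat, n = n, var_y = yty / n)
  ss <- suff_from_effect_summary(sd, matrix(1, 1, 1))
  expect_equal(drop(ss$XtX), xtx, tolerance = 1e-8)
  expect_equal(ss$Xty, xty, tolerance = 1e-8)
  expect_equal(ss$yty, yty, tolerance = 1e-8)

  # zero effects give zero Xty
  sd0 <- summary_data(bhat = c(0, 0), shat = c(0.1, 0.2), n = 50)
  ss0 <- suff_from_effect_summary(sd0, diag(2))
  expect_equal(ss0$Xty, c(0, 0))

  # under standardization the two summary routes coincide
  set.seed(4)
  X <- simulate_genotypes(200, 6, list(type = "block", rho = 0.7, block_size = 3))
  yv <- rnorm(200) + 0.5 * X[, 2]
  Xs <- scale(X, center = TRUE, scale = FALSE)
  Xs <- sweep(Xs, 2, sqrt(colMeans(Xs^2)), "/")
  ys <- yv - mean(yv); ys <- ys / sqrt(mean(ys^2))
  sds <- summarize_study(Xs, ys)
  R <- cor(Xs)
  a <- suff_from_effect_summary(sds, R)
  b <- suff_from_standardized_summary(pve_adjusted_z(sds$z, sds$n), R, sds$n)
  expect_equal(a$XtX, b$XtX, tolerance = 1e-6)
  expect_equal(a$Xty, b$Xty, tolerance = 1e-6)
  expect_equal(a$yty, b$yty, tolerance = 1e-6)
})

test_that("constructors reject dimension mismatches and invalid matrices", {
  expect_error(suff_stats(diag(2), c(1, 2, 3), 1, 10), class = "fm_input_error")
  expect_error(suff_stats(matrix(1:6, 2, 3), c(1, 2), 1, 10),
               class = "fm_input_error")
  expect_error(suff_stats(matrix(c(1, 2, 0, 1), 2, 2), c(1, 2), 1, 10),
               class = "fm_validation_error")
  expect_error(suff_stats(diag(2), c(1, 2), -1, 10), class = "fm_validation_error")
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.4, 1), 2, 2)),
               class = "fm_validation_error")
  expect_error(ld_matrix(matrix(c(1, 2, 2, 1), 2, 2)),
               class = "fm_validation_error")
  expect_error(ld_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)),
               class = "fm_validation_error")
  expect_silent(ld_matrix(matrix(c(1, -0.3, -0.3, 1), 2, 2)))
})
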