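# The synthetic-data generator: LD structure, phenotype calibration,
# study summaries, panels, allele flips, determinism.

test_that("genotype simulation is deterministic and respects the LD model", {
  X1 <- simulate_genotypes(500, 30, seed = 7)
  X2 <- simulate_genotypes(500, 30, seed = 7)
  expect_identical(X1, X2)
  expect_true(all(X1 %in% 0:2))

  # independent model: no LD beyond sampling noise
  Xi <- simulate_genotypes(2000, 20, list(type = "independent"), seed = 8)
  Ri <- cor(Xi)
  expect_lt(mean(abs(Ri[upper.tri(Ri)])), 3 / sqrt(2000))

  # strong AR(1) blocks: at least one pair above 0.9
  Xb <- simulate_genotypes(2000, 20,
    list(type = "block", rho = 0.98, block_size = 10), seed = 9)
  Rb <- cor(Xb)
  expect_gt(max(abs(Rb[upper.tri(Rb)])), 0.9)
  # blocks are independent of each other
  expect_lt(max(abs(Rb[1:10, 11:20])), 0.2)

  expect_error(simulate_genotypes(100, 10, maf_range = c(0.6, 0.7)),
               class = "fm_input_error")
})

test_that("phenotype simulation hits the target PVE", {
  X <- simulate_genotypes(5000, 15, seed = 10)
  # pve = 0: pure noise
  ph0 <- simulate_phenotype(X, c(1, 5), pve = 0, seed = 1)
  expect_equal(ph0$b_true, rep(0, 15))

  # realized PVE concentrates on the target
  pves <- vapply(1:60, function(s) {
    ph <- simulate_phenotype(X, c(2, 9), pve = 0.1, seed = s)
    xb <- drop(scale(X[, c(2, 9)], scale = FALSE) %*% ph$b_true[c(2, 9)])
    var(xb) / var(ph$y)
  }, numeric(1))
  expect_equal(mean(pves), 0.1, tolerance = 0.1)

  # doubling the noise variance at fixed b halves the variance ratio
  ph <- simulate_phenotype(X, 3, pve = 0.2, seed = 2)
  xb <- drop(X %*% ph$b_true)
  r1 <- var(xb) / (var(xb) + 1)
  r2 <- var(xb) / (var(xb) + 2)
  expect_equal((r1 / (1 - r1)) / (r2 / (1 - r2)), 2, tolerance = 1e-10)

  expect_error(simulate_phenotype(X, 1, pve = 1), class = "fm_input_error")
})

test_that("study summaries match per-SNP regression oracles", {
  set.seed(11)
  X <- simulate_genotypes(400, 10, seed = 12)
  ph <- simulate_phenotype(X, 4, pve = 0.1, seed = 13)
  sd <- summarize_study(X, ph$y)
  expect_equal(sd$n, 400)
  # per-SNP oracle: lm on centered data, with the N-denominator error scale
  for (j in c(1, 4, 9)) {
    x <- X[, j] - mean(X[, j]); y <- ph$y - mean(ph$y)
    b <- sum(x * y) / sum(x^2)
    s <- sqrt(sum((y - x * b)^2) / (400 * sum(x^2)))
    expect_equal(sd$bhat[j], b, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sd$shat[j], s, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sd$z[j], b / s, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # y orthogonal to a column gives bhat = 0
  x1 <- c(rep(1, 5), rep(-1, 5))
  Xo <- cbind(a = x1, b = rnorm(10))
  yo <- rep(c(0.5, -0.5), 5) * 0 + rnorm(10)
  yo <- yo - x1 * sum(x1 * (yo - mean(yo))) / sum(x1^2)  # orthogonalize
  sdo <- summarize_study(Xo, yo)
  expect_equal(sdo$bhat[1], 0, tolerance = 1e-10, ignore_attr = TRUE)

  # null-trait z-scores are approximately standard normal
  set.seed(14)
  zs <- replicate(300, summarize_study(X[1:200, 1:3], rnorm(200))$z)
  expect_gt(mean(zs^2), 0.85)
  expect_lt(mean(zs^2), 1.15)

  # monomorphic SNPs are flagged with missing statistics
  Xm <- cbind(mono = rep(1, 50), poly = rbinom(50, 2, 0.4))
  expect_warning(sdm <- summarize_study(Xm, rnorm(50)), "mono")
  expect_true(is.na(sdm$bhat[1]))
  expect_equal(attr(sdm, "monomorphic"), 1L, ignore_attr = TRUE)
})

test_that("allele flips negate correlations and are involutions", {
  X <- simulate_genotypes(800, 12, seed = 15)
  Xf <- inject_allele_flip(X, 5)
  expect_equal(inject_allele_flip(Xf, 5), X, ignore_attr = TRUE)

  R <- panel_ld(X)
  Rf <- panel_ld(Xf)
  expect_equal(Rf[5, -5], -R[5, -5], tolerance = 1e-12)
  expect_equal(Rf[-5, -5], R[-5, -5], tolerance = 1e-12)
  expect_equal(Rf[5, 5], 1)
  expect_equal(flip_ld_snp(R, 5), Rf, tolerance = 1e-12)

  # summary_data method: sign change and allele swap
  sd <- summary_data(snp = c("a", "b"), bhat = c(0.2, -0.1),
                     shat = c(0.1, 0.1), z = c(2, -1),
                     a1 = c("A", "C"), a2 = c("G", "T"))
  sdf <- inject_allele_flip(sd, 2)
  expect_equal(sdf$z, c(2, 1))
  expect_equal(sdf$bhat, c(0.2, 0.1))
  expect_equal(sdf$a1[2], "T")
  expect_equal(inject_allele_flip(sdf, 2), sd)

  expect_error(inject_allele_flip(X, 0), class = "fm_input_error")
})

test_that("whole-dataset simulation is deterministic and self-consistent", {
  sc <- sim_scenario(n_study = 300, n_panel = 150, J = 30, pve = 0.2,
                     n_causal = 2, seed = 16)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$R_panel, d2$R_panel)
  expect_equal(length(d1$causal_idx), 2)
  expect_equal(dim(d1$X), c(300, 30))
  expect_equal(dim(d1$X_panel), c(150, 30))
  expect_equal(diag(d1$R_insample), rep(1, 30), ignore_attr = TRUE)
})

test_that("an allele flip corrupts fine-mapping and repairing the panel fixes it", {
  # one causal SNP, one flipped high-LD non-causal SNP in the panel:
  # the unrepaired fit adds spurious credible sets including the flipped
  # SNP; with the corrected panel a single CS contains the causal SNP
  n_rep <- 10
  bad_has_flip <- 0
  ok_single <- 0
  for (i in seq_len(n_rep)) {
    set.seed(5000 + i)
    ldm <- list(type = "block", rho = 0.9, block_size = 10)
    X <- simulate_genotypes(4000, 100, ldm)
    causal <- 45; flip <- 47
    ph <- simulate_phenotype(X, causal, pve = 0.02)
    sd <- summarize_study(X, ph$y)
    Xp <- simulate_genotypes(1000, 100, ldm)
    Rf <- panel_ld(inject_allele_flip(Xp, flip))
    Rok <- panel_ld(Xp)
    f_bad <- fit_susie_rss(z = sd$z, R = Rf, n = sd$n)
    f_ok <- fit_susie_rss(z = sd$z, R = Rok, n = sd$n)
    cs_bad <- collect_credible_sets(f_bad, Rf)
    cs_ok <- collect_credible_sets(f_ok, Rok)
    if (length(cs_bad) >= 2 &&
        flip %in% unlist(lapply(cs_bad, `[[`, "snp_indices")))
      bad_has_flip <- bad_has_flip + 1
    if (length(cs_ok) == 1 && causal %in% cs_ok[[1]]$snp_indices)
      ok_single <- ok_single + 1
  }
  expect_gt(bad_has_flip / n_rep, 0.5)
  expect_gt(ok_single / n_rep, 0.5)
})

test_that("fits on simulated sufficient statistics recover the causal SNP", {
  # power analogue at high PVE: the causal SNP lands in a credible set
  hits <- vapply(1:12, function(s) {
    dat <- simulate_dataset(sim_scenario(n_study = 2500, n_panel = 200, J = 200,
                                         pve = 0.1, n_causal = 1, seed = 100 + s))
    ss <- suff_from_individual(dat$X, dat$y, standardize = TRUE)
    fit <- fit_susie_ss(ss, mode = "sufficient")
    css <- collect_credible_sets(fit, dat$R_insample)
    any(vapply(css, function(cs) dat$causal_idx %in% cs$snp_indices, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
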