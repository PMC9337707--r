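# Synthetic fine-mapping data with realistic LD structure.
#
# Genotypes are Gaussian-copula threshold dosages: two latent haplotype
# draws from a correlated multivariate normal are thresholded at each
# SNP's minor allele frequency and summed to a 0/1/2 dosage. This
# reproduces the feature fine-mapping methods are sensitive to -- strong,
# block-structured correlation between SNPs -- without requiring real
# genotypes. It does not reproduce other features of real data (rare
# variants, population structure, imputation error).

#' Simulation scenario
#'
#' Bundle of generator settings. The defaults emulate a single
#' fine-mapping region with strong block LD, moderate power (a handful of
#' causal SNPs explaining 10% of trait variance in a study of 2,500, the
#' same signal-to-noise as very small effects in a biobank-scale study),
#' and a 1,000-sample reference panel.
#'
#' @param n_study Study sample size.
#' @param n_panel Reference panel sample size.
#' @param J Number of SNPs.
#' @param ld_model List with `type` (`"block"`, `"ar1"` or
#'   `"independent"`), adjacent-SNP dosage correlation `rho` (applied on
#'   the latent scale with attenuation correction), and `block_size`.
#' @param n_causal Number of causal SNPs (1-3), or `NULL` to draw
#'   uniformly from 1:3 per dataset.
#' @param pve Total proportion of trait variance explained by the causal
#'   SNPs, in `[0, 1)`.
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param seed Integer seed controlling the whole dataset.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_study = 2500, n_panel = 1000, J = 200,
                         ld_model = list(type = "block", rho = 0.95,
                                         block_size = 10),
                         n_causal = NULL, pve = 0.1,
                         maf_range = c(0.1, 0.5), seed = 1) {
  if (pve < 0 || pve >= 1) fm_stop_input("pve must lie in [0, 1)")
  if (!is.null(n_causal) && (n_causal < 1 || n_causal > J))
    fm_stop_input("n_causal must lie in 1..J")
  structure(list(n_study = n_study, n_panel = n_panel, J = J,
                 ld_model = ld_model, n_causal = n_causal, pve = pve,
                 maf_range = maf_range, seed = seed),
            class = "sim_scenario")
}

# Latent standard-normal matrix with AR(1) correlation within blocks,
# generated by the recursion z_j = rho z_{j-1} + sqrt(1 - rho^2) e_j.
# Thresholding attenuates correlation (for thresholds at the median the
# dosage correlation is 2/pi * asin(rho_latent)), so the user-facing rho
# -- the approximate adjacent-SNP dosage LD -- is mapped to the latent
# scale by the inverse transform sin(pi/2 * rho).
latent_ld_normal <- function(n, J, ld_model) {
  type <- ld_model$type %||% "block"
  if (type == "independent")
    return(matrix(stats::rnorm(n * J), n, J))
  rho <- ld_model$rho %||% 0.95
  if (rho < 0 || rho >= 1) fm_stop_input("ld_model$rho must lie in [0, 1)")
  rho <- sin(pi / 2 * rho)
  bs <- if (type == "ar1") J else ld_model$block_size %||% 10
  Z <- matrix(stats::rnorm(n * J), n, J)
  for (j in seq_len(J)[-1]) {
    if ((j - 1) %% bs != 0)  # block boundaries restart the chain
      Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  }
  Z
}

#' Simulate LD-structured genotype dosages
#'
#' Draws minor allele frequencies uniformly from `maf_range`, then builds
#' each individual's dosage at SNP j as the sum of two latent-Gaussian
#' haplotype indicators thresholded at `qnorm(1 - maf_j)`. AR(1)
#' correlation within blocks (with `rho` corrected for threshold
#' attenuation, so it approximates the adjacent-SNP dosage LD) induces
#' block LD; with `rho` near 1 adjacent SNPs exceed `|r| = 0.9`.
#'
#' @param n Number of individuals (>= 2).
#' @param J Number of SNPs.
#' @param ld_model See [sim_scenario()].
#' @param maf_range Minor allele frequency range within (0, 0.5].
#' @param seed Integer seed, or `NULL` to use the ambient RNG.
#' @return n x J dosage matrix (0/1/2) with columns named `snp1..snpJ`.
#' @export
simulate_genotypes <- function(n, J, ld_model = list(type = "block",
                                                     rho = 0.95,
                                                     block_size = 10),
                               maf_range = c(0.1, 0.5), seed = NULL) {
  if (n < 2 || J < 1) fm_stop_input("need n >= 2 and J >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    fm_stop_input("maf_range must be an increasing pair within (0, 0.5]")
  with_seed(seed, {
    maf <- stats::runif(J, maf_range[1], maf_range[2])
    thr <- stats::qnorm(1 - maf)
    h1 <- latent_ld_normal(n, J, ld_model)
    h2 <- latent_ld_normal(n, J, ld_model)
    X <- sweep(h1, 2, thr, ">") + sweep(h2, 2, thr, ">")
    storage.mode(X) <- "double"
    colnames(X) <- paste0("snp", seq_len(J))
    attr(X, "maf") <- maf
    X
  })
}

#' Simulate a quantitative trait with sparse causal effects
#'
#' Draws i.i.d. normal effect sizes for the causal SNPs, rescales them so
#' the genetic variance component equals `pve / (1 - pve)` times the
#' residual variance (`sigma2 = 1`) in the realized sample, and adds
#' Gaussian noise. The expected sample proportion of variance explained is
#' therefore `pve`.
#'
#' @param X Genotype matrix.
#' @param causal_idx Column indices of the causal SNPs.
#' @param pve Target total proportion of variance explained, in `[0, 1)`.
#' @param seed Integer seed, or `NULL`.
#' @return List with `y` (length n), `b_true` (length J, zeros off the
#'   causal set), and `sigma2_true` (= 1).
#' @export
simulate_phenotype <- function(X, causal_idx, pve, seed = NULL) {
  if (pve < 0 || pve >= 1) fm_stop_input("pve must lie in [0, 1)")
  J <- ncol(X)
  if (length(causal_idx) > 0 && any(causal_idx < 1 | causal_idx > J))
    fm_stop_input("causal_idx out of range")
  n <- nrow(X)
  with_seed(seed, {
    b <- numeric(J)
    sigma2 <- 1
    if (pve > 0 && length(causal_idx) > 0) {
      b0 <- stats::rnorm(length(causal_idx))
      Xc <- scale(X[, causal_idx, drop = FALSE], center = TRUE, scale = FALSE)
      xb <- drop(Xc %*% b0)
      v <- mean(xb^2)
      if (v <= 0) fm_stop_input("causal SNPs are monomorphic; cannot reach target pve")
      b[causal_idx] <- b0 * sqrt(pve / (1 - pve) * sigma2 / v)
    }
    y <- drop(X %*% b) + stats::rnorm(n, sd = sqrt(sigma2))
    list(y = y, b_true = b, sigma2_true = sigma2)
  })
}

#' Single-SNP association summaries of a study
#'
#' Centers the data and computes, per SNP, the simple-regression effect
#' estimate `bhat_j = x_j'y / x_j'x_j`, its standard error (with the
#' sample size in the denominator) and the z-score, plus the sample size
#' and phenotype variance. Monomorphic SNPs are flagged with a warning and
#' get missing statistics.
#'
#' @param X Genotype matrix (centered internally).
#' @param y Phenotype vector (centered internally).
#' @return A [summary_data()] object; if monomorphic SNPs are present the
#'   object carries their indices in attribute `"monomorphic"` and `NA`
#'   statistics at those positions.
#' @export
summarize_study <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) fm_stop_input("nrow(X) must equal length(y)")
  ids <- colnames(X) %||% paste0("snp", seq_len(ncol(X)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  yty <- sum(yc^2)
  d <- colSums(Xc^2)
  mono <- which(d <= 0)
  dm <- ifelse(d > 0, d, NA_real_)
  xty <- drop(crossprod(Xc, yc))
  bhat <- xty / dm
  shat <- sqrt(pmax(yty - bhat^2 * dm, 0) / (n * dm))
  if (length(mono) > 0) {
    warning("monomorphic SNP(s) with missing statistics: ",
            paste(ids[mono], collapse = ", "))
    out <- structure(
      list(snp = ids, bhat = bhat, shat = shat, z = bhat / shat, n = n,
           var_y = yty / n, a1 = NULL, a2 = NULL, J = length(ids)),
      class = "summary_data")
    attr(out, "monomorphic") <- mono
    return(out)
  }
  sd <- summary_data(snp = ids, bhat = bhat, shat = shat, z = bhat / shat,
                     n = n, var_y = yty / n)
  sd
}

#' Sample LD matrix of a reference panel
#'
#' The SNP-by-SNP Pearson correlation matrix of panel dosages.
#'
#' @param X_panel Panel genotype matrix (disjoint from the study sample).
#' @return J x J correlation matrix with unit diagonal.
#' @export
panel_ld <- function(X_panel) {
  if (!is.matrix(X_panel)) X_panel <- as.matrix(X_panel)
  d <- apply(X_panel, 2, stats::sd)
  bad <- which(d <= 0)
  if (length(bad) > 0) {
    ids <- colnames(X_panel) %||% paste0("snp", seq_len(ncol(X_panel)))
    fm_stop_validation(sprintf("monomorphic panel SNP(s): %s",
                               paste(ids[bad], collapse = ", ")))
  }
  R <- stats::cor(X_panel)
  (R + t(R)) / 2
}

#' Inject an allele flip
#'
#' Recodes the allele encoding of one SNP, emulating a mismatch between
#' the study sample and the LD reference panel. For a genotype (dosage)
#' matrix, dosages are recoded `g -> 2 - g`, which negates that SNP's
#' correlations with every other SNP while leaving its variance unchanged.
#' For a [summary_data()] object, the marginal effect and z-score change
#' sign and the allele labels swap. Applying the flip twice restores the
#' original object.
#'
#' @param x A dosage matrix or a `summary_data` object.
#' @param j SNP (column) index to flip.
#' @return A modified copy of `x`.
#' @export
inject_allele_flip <- function(x, j) UseMethod("inject_allele_flip")

#' @export
inject_allele_flip.matrix <- function(x, j) {
  if (length(j) != 1 || j < 1 || j > ncol(x)) fm_stop_input("j out of range")
  x[, j] <- 2 - x[, j]
  x
}

#' @export
inject_allele_flip.summary_data <- function(x, j) {
  if (length(j) != 1 || j < 1 || j > x$J) fm_stop_input("j out of range")
  if (!is.null(x$bhat)) x$bhat[j] <- -x$bhat[j]
  if (!is.null(x$z)) x$z[j] <- -x$z[j]
  if (!is.null(x$a1) && !is.null(x$a2)) {
    tmp <- x$a1[j]; x$a1[j] <- x$a2[j]; x$a2[j] <- tmp
  }
  x
}

#' Flip one SNP's sign in an LD matrix
#'
#' Negates the off-diagonal entries of row and column `j`, the effect an
#' allele flip in the panel has on the panel correlation matrix.
#'
#' @param R LD matrix.
#' @param j SNP index.
#' @return The modified matrix.
#' @export
flip_ld_snp <- function(R, j) {
  if (length(j) != 1 || j < 1 || j > nrow(R)) fm_stop_input("j out of range")
  R[j, ] <- -R[j, ]
  R[, j] <- -R[, j]          # the diagonal entry is negated twice: unchanged
  R
}

#' Simulate a complete fine-mapping dataset
#'
#' Runs the full generative pipeline for one region: study genotypes,
#' causal effects and phenotype, single-SNP summary statistics, in-sample
#' LD, and a disjoint reference panel with its LD matrix. Fully
#' deterministic given `scenario$seed`.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `X`, `y`, `b_true`, `sigma2_true`, `causal_idx`,
#'   `summary` (a [summary_data()]), `R_insample`, `X_panel`, `R_panel`,
#'   and the `scenario`.
#' @export
simulate_dataset <- function(scenario = sim_scenario()) {
  if (!inherits(scenario, "sim_scenario"))
    fm_stop_input("scenario must be a sim_scenario")
  with_seed(scenario$seed, {
    nc <- scenario$n_causal %||% sample(1:3, 1)
    X <- simulate_genotypes(scenario$n_study, scenario$J, scenario$ld_model,
                            scenario$maf_range)
    causal_idx <- sort(sample(scenario$J, nc))
    ph <- simulate_phenotype(X, causal_idx, scenario$pve)
    Xp <- simulate_genotypes(scenario$n_panel, scenario$J, scenario$ld_model,
                             scenario$maf_range)
    list(X = X, y = ph$y, b_true = ph$b_true, sigma2_true = ph$sigma2_true,
         causal_idx = causal_idx, summary = summarize_study(X, ph$y),
         R_insample = panel_ld(X), X_panel = Xp, R_panel = panel_ld(Xp),
         scenario = scenario)
  })
}
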