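# Diagnostics for inconsistencies between z-scores and the LD matrix.
#
# Under the null multivariate normal model z ~ N(0, R), the conditional
# distribution of each z-score given all the others has mean
# -Omega[j,-j] z[-j] / Omega[jj] and variance 1 / Omega[jj], where
# Omega = R^{-1}. Large standardized deviations from the conditional mean
# flag SNPs whose z-score is inconsistent with the LD matrix (wrong
# sample, allele flip, ...). These expressions assume the SNP's own true
# effect is negligible or that it is in strong LD with other SNPs.

solve_ld <- function(Rlam) {
  ch <- tryCatch(chol(Rlam), error = function(e) NULL)
  if (is.null(ch))
    fm_stop_numerical(paste0(
      "LD matrix is numerically singular or not positive definite; ",
      "regularize it first (see regularize_ld / estimate_lambda)"))
  chol2inv(ch)
}

#' Conditional expectation and variance of each z-score given the others
#'
#' For `Omega = Rlam^{-1}`, returns `expected_z_j = -Omega[j,-j] z[-j] /
#' Omega[jj]` and `cond_var_j = 1 / Omega[jj]` for all SNPs, computed from
#' a single Cholesky factorization. `Rlam` must be invertible; apply
#' [regularize_ld()] with an estimated level first when it is not.
#'
#' @param z_adj (PVE-adjusted) z-scores.
#' @param Rlam Invertible LD matrix (possibly regularized).
#' @return List with numeric vectors `expected_z` and `cond_var`.
#' @export
conditional_z <- function(z_adj, Rlam) {
  J <- nrow(Rlam)
  if (length(z_adj) != J) fm_stop_input("length(z_adj) must match dim(Rlam)")
  if (J > 5000)
    warning("inverting a ", J, " x ", J, " LD matrix; this may be expensive")
  omega <- solve_ld(Rlam)
  ojj <- diag(omega)
  # -Omega[j,-j] z[-j] / Omega[jj] = z_j - (Omega z)_j / Omega[jj]
  oz <- drop(omega %*% z_adj)
  list(expected_z = z_adj - oz / ojj, cond_var = 1 / ojj)
}

#' Standardized discordance statistics
#'
#' `t_j = (z_j - expected_z_j) / sqrt(cond_var_j)`, approximately standard
#' normal when the z-scores and LD matrix are consistent. SNPs with the
#' largest `|t_j|` are the most likely to violate the model assumptions.
#'
#' @inheritParams conditional_z
#' @return J-vector of t statistics.
#' @export
z_discordance <- function(z_adj, Rlam) {
  cz <- conditional_z(z_adj, Rlam)
  (z_adj - cz$expected_z) / sqrt(cz$cond_var)
}

#' Allele-flip likelihood ratios
#'
#' Compares, per SNP, the conditional density of the observed z-score
#' under a sign-flipped relationship with the LD matrix (conditional mean
#' negated) against the unflipped model:
#' `LR_j = N(z_j; -expected_z_j, cond_var_j) / N(z_j; expected_z_j,
#' cond_var_j) = exp(-2 z_j expected_z_j / cond_var_j)`. Values above 1
#' flag candidate allele flips; the statistic is uninformative
#' (`LR_j = 1`) when the conditional mean is 0, and flipping the sign of
#' `z_j` maps `LR_j` to `1 / LR_j` exactly.
#'
#' @inheritParams conditional_z
#' @return J-vector of likelihood ratios (non-negative).
#' @export
allele_flip_lr <- function(z_adj, Rlam) {
  cz <- conditional_z(z_adj, Rlam)
  exp(-2 * z_adj * cz$expected_z / cz$cond_var)
}

#' Per-SNP summary-data consistency report
#'
#' Assembles the conditional expectations, discordance statistics and
#' allele-flip likelihood ratios into one table, ranks SNPs by `|t|`
#' descending, and marks as candidates the SNPs with `LR > 1` among those
#' with `|z| > z_threshold`. The `z` and `expected_z` columns are the
#' plot-ready observed-vs-expected pairs.
#'
#' @inheritParams conditional_z
#' @param z_threshold Minimum `|z|` for a SNP to be flagged as an
#'   allele-flip candidate (default 2).
#' @param snp Optional SNP identifiers.
#' @return A data frame with columns `snp`, `z`, `expected_z`, `cond_var`,
#'   `t`, `flip_lr`, `rank` (1 = most discordant) and `candidate`, in
#'   input SNP order.
#' @export
diagnostic_table <- function(z_adj, Rlam, z_threshold = 2, snp = NULL) {
  cz <- conditional_z(z_adj, Rlam)
  tstat <- (z_adj - cz$expected_z) / sqrt(cz$cond_var)
  lr <- exp(-2 * z_adj * cz$expected_z / cz$cond_var)
  data.frame(
    snp = snp %||% paste0("snp", seq_along(z_adj)),
    z = z_adj,
    expected_z = cz$expected_z,
    cond_var = cz$cond_var,
    t = tstat,
    flip_lr = lr,
    rank = rank(-abs(tstat), ties.method = "first"),
    candidate = lr > 1 & abs(z_adj) > z_threshold,
    stringsAsFactors = FALSE)
}
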