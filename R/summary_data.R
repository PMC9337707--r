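#' Per-SNP summary statistics from a single-SNP association scan
#'
#' Bundles and validates the marginal association statistics that
#' summary-data fine-mapping consumes: per-SNP simple-regression effect
#' estimates `bhat` and standard errors `shat` (computed with the sample
#' size, not N - 2, in the denominator of the residual variance), and/or
#' z-scores `z = bhat/shat`, optionally with the study sample size `n`,
#' the sample variance of the phenotype `var_y`, and allele labels.
#'
#' Allele labels are carried through unchanged; the package never
#' re-harmonizes alleles because mismatched encodings between a study and
#' an LD reference panel are precisely what [diagnostic_table()] detects.
#'
#' @param snp Character vector of SNP identifiers (optional).
#' @param bhat Numeric vector of marginal effect estimates (optional if
#'   `z` is given).
#' @param shat Numeric vector of standard errors, strictly positive
#'   (required with `bhat`).
#' @param z Numeric vector of z-scores (optional if `bhat`/`shat` given).
#' @param n Study sample size (optional).
#' @param var_y Sample variance of the phenotype (optional).
#' @param a1,a2 Allele labels per SNP (optional).
#'
#' @return An object of class `"summary_data"`: a list with the validated
#'   fields above and the number of SNPs `J`.
#' @seealso [zscores_from_effects()], [suff_from_effect_summary()],
#'   [read_summary_tsv()]
#' @export
#' @examples
#' sd <- summary_data(bhat = c(0.3, -0.4), shat = c(0.1, 0.2))
#' zscores_from_effects(sd)  # c(3, -2)
summary_data <- function(snp = NULL, bhat = NULL, shat = NULL, z = NULL,
                         n = NULL, var_y = NULL, a1 = NULL, a2 = NULL) {
  has_bs <- !is.null(bhat) || !is.null(shat)
  if (has_bs && (is.null(bhat) || is.null(shat)))
    fm_stop_input("bhat and shat must be provided together")
  if (!has_bs && is.null(z))
    fm_stop_input("provide either (bhat and shat) or z")

  lens <- c(
    if (!is.null(snp)) length(snp),
    if (!is.null(bhat)) length(bhat),
    if (!is.null(shat)) length(shat),
    if (!is.null(z)) length(z),
    if (!is.null(a1)) length(a1),
    if (!is.null(a2)) length(a2))
  J <- unique(lens)
  if (length(J) != 1L)
    fm_stop_input("all per-SNP vectors must have a common length")

  ids <- snp %||% paste0("snp", seq_len(J))
  if (!is.null(shat)) {
    bad <- which(!is.finite(shat) | shat <= 0)
    if (length(bad) > 0)
      fm_stop_validation(sprintf(
        "standard errors must be strictly positive; offending SNP(s): %s",
        paste(ids[bad], collapse = ", ")))
  }
  if (!is.null(bhat) && any(!is.finite(bhat)))
    fm_stop_validation("bhat contains missing or non-finite values; remove these SNPs upstream")
  if (!is.null(z) && any(!is.finite(z)))
    fm_stop_validation("z contains missing or non-finite values; remove these SNPs upstream")
  if (!is.null(z) && !is.null(bhat)) {
    zq <- bhat / shat
    if (max(abs(z - zq)) > 1e-6 * max(1, max(abs(zq))))
      fm_stop_validation("z is inconsistent with bhat/shat")
  }
  if (!is.null(n)) n <- check_scalar_count(n, "n")
  if (!is.null(var_y) && (length(var_y) != 1L || !is.finite(var_y) || var_y <= 0))
    fm_stop_input("var_y must be a single positive value")

  structure(
    list(snp = snp, bhat = bhat, shat = shat, z = z, n = n, var_y = var_y,
         a1 = a1, a2 = a2, J = J),
    class = "summary_data")
}

#' @export
print.summary_data <- function(x, ...) {
  cat(sprintf("summary_data: %d SNPs; fields: %s\n", x$J,
              paste(names(Filter(Negate(is.null), x[c("bhat", "shat", "z", "n", "var_y")])),
                    collapse = ", ")))
  invisible(x)
}

#' z-scores from marginal effects and standard errors
#'
#' Computes `z_j = bhat_j / shat_j` for each SNP.
#'
#' @param sd A [summary_data()] object with `bhat` and `shat` present.
#' @return Numeric vector of z-scores.
#' @export
zscores_from_effects <- function(sd) {
  if (!inherits(sd, "summary_data")) fm_stop_input("sd must be a summary_data object")
  if (is.null(sd$bhat) || is.null(sd$shat))
    fm_stop_input("bhat and shat are required to compute z-scores")
  sd$bhat / sd$shat
}

#' PVE-adjusted z-scores
#'
#' Shrinks each z-score by the factor `sqrt(n / (n + z_j^2))`, i.e. by the
#' square root of one minus the per-SNP estimated proportion of phenotypic
#' variance explained. The adjusted z-scores satisfy the exact identity
#' `X'y = sqrt(n) * z_adj` when genotypes and phenotype are standardized,
#' whereas the raw z-scores only satisfy it approximately. When all effects
#' are small the adjustment is negligible.
#'
#' When `n` is `NULL` the raw z-scores are returned with a warning; this is
#' an acceptable approximation when the sample size is unknown and the
#' per-SNP effects are small.
#'
#' @param z Numeric vector of z-scores.
#' @param n Sample size (positive), or `NULL`.
#' @return Numeric vector of adjusted z-scores, same length and signs as
#'   `z`, with `|z_adj| <= |z|`.
#' @export
#' @examples
#' pve_adjusted_z(c(2), n = 4)  # 2 * sqrt(4/8) = sqrt(2)
pve_adjusted_z <- function(z, n) {
  if (is.null(n)) {
    warning("sample size unknown; using unadjusted z-scores in place of PVE-adjusted z-scores")
    return(z)
  }
  n <- check_scalar_count(n, "n")
  z * sqrt(n / (n + z^2))
}

#' Validate an LD (SNP correlation) matrix
#'
#' Checks symmetry, unit diagonal and entries in `[-1, 1]`, and attaches
#' the regularization level and provenance as attributes.
#'
#' @param R Square numeric matrix of SNP-by-SNP correlations.
#' @param lam Regularization level in `[0, 1]` already applied to `R`.
#' @param source `"in_sample"` if computed from the study genotypes,
#'   `"reference_panel"` otherwise.
#' @param tol Numerical tolerance for the checks.
#' @return The matrix `R` with attributes `lam` and `source`.
#' @export
ld_matrix <- function(R, lam = 0, source = c("in_sample", "reference_panel"),
                      tol = 1e-6) {
  source <- match.arg(source)
  if (!is.matrix(R) || nrow(R) != ncol(R))
    fm_stop_input("R must be a square matrix")
  if (!is_symmetric_tol(R, tol))
    fm_stop_validation("LD matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > tol)
    fm_stop_validation("LD matrix diagonal entries must all equal 1")
  if (max(abs(R)) > 1 + tol)
    fm_stop_validation("LD matrix entries must lie in [-1, 1]")
  if (length(lam) != 1L || !is.finite(lam) || lam < 0 || lam > 1)
    fm_stop_input("lam must lie in [0, 1]")
  attr(R, "lam") <- lam
  attr(R, "source") <- source
  R
}

#' Sufficient statistics for the multiple-regression likelihood
#'
#' The quadruple (X'X, X'y, y'y, N) determines the Gaussian multiple
#' regression likelihood completely, so model fitting from these four
#' quantities reproduces fitting from the individual-level data exactly.
#'
#' @param XtX J x J symmetric matrix.
#' @param Xty J-vector.
#' @param yty Non-negative scalar.
#' @param n Sample size (>= 1).
#' @param snp Optional SNP identifiers.
#' @return An object of class `"suff_stats"`.
#' @export
suff_stats <- function(XtX, Xty, yty, n, snp = NULL) {
  if (!is.matrix(XtX) || nrow(XtX) != ncol(XtX))
    fm_stop_input("XtX must be a square matrix")
  if (!is_symmetric_tol(XtX))
    fm_stop_validation("XtX must be symmetric")
  if (any(diag(XtX) < 0))
    fm_stop_validation("diag(XtX) must be non-negative")
  if (length(Xty) != nrow(XtX))
    fm_stop_input("length(Xty) must match nrow(XtX)")
  if (length(yty) != 1L || !is.finite(yty) || yty < 0)
    fm_stop_validation("yty must be a non-negative scalar")
  n <- check_scalar_count(n, "n")
  if (!is.null(snp) && length(snp) != length(Xty))
    fm_stop_input("snp must have one id per SNP")
  structure(list(XtX = XtX, Xty = as.numeric(Xty), yty = as.numeric(yty),
                 n = n, snp = snp, J = length(Xty)),
            class = "suff_stats")
}

#' @export
print.suff_stats <- function(x, ...) {
  cat(sprintf("suff_stats: J = %d SNPs, n = %g, yty = %.4g\n", x$J, x$n, x$yty))
  invisible(x)
}

#' Sufficient statistics from individual-level data
#'
#' Centers `y` and the columns of `X` to mean zero (optionally scaling both
#' to unit variance, with the sample size N in the variance denominator)
#' and forms (X'X, X'y, y'y, N).
#'
#' @param X N x J genotype (dosage) matrix.
#' @param y N-vector phenotype.
#' @param standardize If `TRUE`, scale the centered `y` and columns of `X`
#'   to unit variance.
#' @return A [suff_stats()] object.
#' @export
suff_from_individual <- function(X, y, standardize = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) fm_stop_input("nrow(X) must equal length(y)")
  if (n < 2) fm_stop_input("at least 2 samples are required")
  ids <- colnames(X) %||% paste0("snp", seq_len(ncol(X)))

  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  if (standardize) {
    sdx <- sqrt(colMeans(Xc^2))  # denominator N, not N - 1
    bad <- which(sdx <= 0)
    if (length(bad) > 0)
      fm_stop_validation(sprintf(
        "cannot standardize zero-variance column(s): %s",
        paste(ids[bad], collapse = ", ")))
    Xc <- sweep(Xc, 2, sdx, "/")
    sy <- sqrt(mean(yc^2))
    if (sy > 0) yc <- yc / sy
  }
  suff_stats(XtX = crossprod(Xc), Xty = drop(crossprod(Xc, yc)),
             yty = sum(yc^2), n = n, snp = ids)
}

#' Sufficient statistics from standardized summary data
#'
#' For standardized genotypes and phenotype the sufficient statistics are
#' exact functions of the LD matrix, the PVE-adjusted z-scores and the
#' sample size: `X'X = n R`, `X'y = sqrt(n) z_adj`, `y'y = n`. With the
#' in-sample LD matrix this reproduces the individual-level likelihood
#' exactly; with a reference-panel LD matrix it approximates it.
#'
#' @param z_adj PVE-adjusted z-scores (see [pve_adjusted_z()]).
#' @param R LD matrix (J x J).
#' @param n Sample size.
#' @param snp Optional SNP identifiers.
#' @return A [suff_stats()] object.
#' @export
suff_from_standardized_summary <- function(z_adj, R, n, snp = NULL) {
  if (length(z_adj) != nrow(R))
    fm_stop_input("length(z_adj) must match the dimension of R")
  n <- check_scalar_count(n, "n")
  suff_stats(XtX = n * R, Xty = sqrt(n) * z_adj, yty = n, n = n, snp = snp)
}

#' Sufficient statistics from effect-scale summary data
#'
#' Reconstructs the per-SNP quantities `x_j'x_j` from the marginal effect
#' estimates and standard errors via the simple-regression identities
#' `bhat_j = x_j'y / x_j'x_j` and
#' `shat_j^2 = (y'y - bhat_j^2 x_j'x_j) / (n x_j'x_j)`, which give
#' `x_j'x_j = y'y / (n shat_j^2 + bhat_j^2)`. The full cross-product matrix
#' is then `X'X = D^{1/2} R D^{1/2}` with `D = diag(x_j'x_j)`, and
#' `X'y_j = x_j'x_j * bhat_j`, `y'y = n * var_y`.
#'
#' @param sd A [summary_data()] object with `bhat` and `shat`.
#' @param R LD matrix.
#' @param n Sample size; defaults to `sd$n`.
#' @param var_y Sample variance of the phenotype; defaults to `sd$var_y`,
#'   then to 1 (standardized-phenotype convention).
#' @return A [suff_stats()] object.
#' @export
suff_from_effect_summary <- function(sd, R, n = sd$n, var_y = NULL) {
  if (!inherits(sd, "summary_data")) fm_stop_input("sd must be a summary_data object")
  if (is.null(sd$bhat) || is.null(sd$shat))
    fm_stop_input("bhat and shat are required; use suff_from_standardized_summary for z-scores")
  n <- check_scalar_count(n, "n")
  var_y <- var_y %||% sd$var_y %||% 1
  if (sd$J != nrow(R))
    fm_stop_input("summary data and LD matrix dimensions differ")
  yty <- n * var_y
  d <- yty / (n * sd$shat^2 + sd$bhat^2)
  bad <- which(!is.finite(d) | d <= 0)
  if (length(bad) > 0) {
    ids <- sd$snp %||% paste0("snp", seq_len(sd$J))
    fm_stop_validation(sprintf(
      "implied x_j'x_j is non-positive for SNP(s): %s",
      paste(ids[bad], collapse = ", ")))
  }
  sq <- sqrt(d)
  XtX <- R * tcrossprod(sq)
  XtX <- (XtX + t(XtX)) / 2
  suff_stats(XtX = XtX, Xty = d * sd$bhat, yty = yty, n = n, snp = sd$snp)
}
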