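# Readers and writers for the package's plain-text interchange formats:
#  - summary TSV: header `snp  a1  a2` plus either `betahat` + `se` or `z`
#  - LD matrix: dense whitespace-delimited J x J numeric text, no header
#  - PIP / credible-set / diagnostic report TSVs

#' Read a single-SNP summary statistics TSV
#'
#' Tab-delimited with a header; columns `snp`, `a1`, `a2`, then either
#' `betahat` and `se`, or `z`.
#'
#' @param path File path.
#' @param n Study sample size (not stored in the file).
#' @param var_y Sample phenotype variance (optional).
#' @return A [summary_data()] object.
#' @export
read_summary_tsv <- function(path, n = NULL, var_y = NULL) {
  if (!file.exists(path)) fm_stop_input(sprintf("summary file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("snp", "a1", "a2") %in% names(dt)))
    fm_stop_input("summary TSV must have columns snp, a1, a2")
  has_bs <- all(c("betahat", "se") %in% names(dt))
  has_z <- "z" %in% names(dt)
  if (!has_bs && !has_z)
    fm_stop_input("summary TSV must have betahat+se or z columns")
  summary_data(snp = as.character(dt$snp),
               bhat = if (has_bs) dt$betahat,
               shat = if (has_bs) dt$se,
               z = if (has_z) dt$z,
               n = n, var_y = var_y,
               a1 = as.character(dt$a1), a2 = as.character(dt$a2))
}

#' Write a summary statistics TSV
#'
#' @param sd A [summary_data()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(sd, path) {
  if (!inherits(sd, "summary_data")) fm_stop_input("sd must be a summary_data object")
  dt <- data.frame(snp = sd$snp %||% paste0("snp", seq_len(sd$J)),
                   a1 = sd$a1 %||% rep("A", sd$J),
                   a2 = sd$a2 %||% rep("G", sd$J))
  if (!is.null(sd$bhat)) { dt$betahat <- sd$bhat; dt$se <- sd$shat }
  if (!is.null(sd$z)) dt$z <- sd$z
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a dense LD matrix from whitespace-delimited text
#'
#' @param path File path (J rows of J numbers, no header).
#' @param validate Check symmetry, unit diagonal, and entry range
#'   (default `TRUE`).
#' @param source Provenance label attached to the matrix.
#' @return J x J numeric matrix.
#' @export
read_ld_matrix <- function(path, validate = TRUE,
                           source = c("reference_panel", "in_sample")) {
  source <- match.arg(source)
  if (!file.exists(path)) fm_stop_input(sprintf("LD file not found: %s", path))
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  R <- as.matrix(dt)
  dimnames(R) <- NULL
  if (!is.numeric(R)) fm_stop_input("LD file must be entirely numeric")
  if (nrow(R) != ncol(R)) fm_stop_input("LD matrix must be square")
  if (validate) R <- ld_matrix(R, source = source)
  R
}

#' Write a dense LD matrix as whitespace-delimited text
#'
#' @param R LD matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(R, path) {
  data.table::fwrite(as.data.frame(R), path, sep = " ", col.names = FALSE)
  invisible(path)
}

#' Write per-SNP posterior inclusion probabilities
#'
#' @param fit A `susie_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pip_tsv <- function(fit, path) {
  dt <- data.frame(snp = fit$snp %||% paste0("snp", seq_len(fit$J)),
                   pip = fit$pip)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write a credible set report TSV
#'
#' Columns `cs_id`, `effect`, `coverage`, `purity`, `n_snps`, `snps`
#' (comma-joined ids).
#'
#' @param css A [collect_credible_sets()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cs_tsv <- function(css, path) {
  data.table::fwrite(as.data.frame(css), path, sep = "\t")
  invisible(path)
}
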