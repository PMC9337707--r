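#' Level-rho credible set for one effect
#'
#' Returns the smallest set of SNPs, taken in decreasing order of posterior
#' assignment probability, whose cumulative probability reaches the
#' coverage level `rho`. Ties in probability are broken by ascending SNP
#' index.
#'
#' @param alpha_row J-vector of assignment probabilities (sums to 1).
#' @param rho Target coverage in (0, 1], default 0.95.
#' @return Integer vector of SNP indices, ordered by decreasing
#'   probability, with attribute `"coverage"` giving the attained mass.
#' @export
credible_set_for_effect <- function(alpha_row, rho = 0.95) {
  if (abs(sum(alpha_row) - 1) > 1e-6)
    fm_stop_input("alpha_row must sum to 1")
  ord <- order(alpha_row, seq_along(alpha_row), decreasing = c(TRUE, FALSE),
               method = "radix")
  k <- which(cumsum(alpha_row[ord]) >= rho)[1]
  if (is.na(k)) k <- length(alpha_row)  # guard against rounding below rho
  idx <- ord[seq_len(k)]
  attr(idx, "coverage") <- sum(alpha_row[idx])
  idx
}

#' Purity of a set of SNPs
#'
#' The smallest absolute pairwise correlation among the SNPs in the set.
#' Singleton sets have purity 1 by convention. For sets larger than
#' `max_subsample` the minimum is computed over a random subsample of SNPs
#' drawn under a fixed internal seed (the pair count grows quadratically).
#'
#' @param indices SNP indices within `1..J`.
#' @param R LD matrix.
#' @param max_subsample Subsampling threshold (default 100 SNPs).
#' @return Scalar purity in `[0, 1]`.
#' @export
cs_purity <- function(indices, R, max_subsample = 100) {
  J <- nrow(R)
  if (any(indices < 1 | indices > J)) fm_stop_input("indices out of range")
  if (length(indices) <= 1) return(1)
  if (length(indices) > max_subsample)
    indices <- with_seed(1742, sample(indices, max_subsample))
  sub <- abs(R[indices, indices])
  min(sub[upper.tri(sub)])
}

#' Credible sets from a fitted model
#'
#' Builds one candidate level-`rho` credible set per non-null effect
#' (effects whose estimated prior variance is 0 are skipped: their
#' assignment probabilities are prior-level noise), computes each set's
#' purity against the LD matrix, discards sets with purity below
#' `min_purity`, and optionally collapses duplicated index sets, keeping
#' the lowest effect index.
#'
#' @param fit A `susie_fit`.
#' @param R LD matrix used for purity.
#' @param rho Target coverage (default 0.95).
#' @param min_purity Minimum purity retained (default 0.5).
#' @param dedupe Collapse identical index sets (default `TRUE`).
#' @param max_subsample Passed to [cs_purity()].
#' @return An object of class `"credible_sets"`: a list of sets, each with
#'   `snp_indices`, `snps` (ids if available), `effect_index`,
#'   `coverage_attained`, and `purity`; sorted by effect index.
#' @export
collect_credible_sets <- function(fit, R, rho = 0.95, min_purity = 0.5,
                                  dedupe = TRUE, max_subsample = 100) {
  if (!inherits(fit, "susie_fit")) fm_stop_input("fit must be a susie_fit")
  if (fit$J != nrow(R)) fm_stop_input("fit and R dimensions differ")
  out <- list()
  seen <- character(0)
  for (l in seq_len(fit$L)) {
    if (fit$prior_vars[l] <= 0) next
    idx <- credible_set_for_effect(fit$alpha[l, ], rho)
    pur <- cs_purity(idx, R, max_subsample)
    if (pur < min_purity) next
    key <- paste(sort(idx), collapse = ",")
    if (dedupe && key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(
      snp_indices = as.integer(idx),
      snps = if (!is.null(fit$snp)) fit$snp[idx] else as.character(idx),
      effect_index = l,
      coverage_attained = as.numeric(attr(idx, "coverage")),
      purity = pur)
  }
  structure(out, class = "credible_sets", rho = rho, min_purity = min_purity)
}

#' @export
print.credible_sets <- function(x, ...) {
  if (length(x) == 0) {
    cat("credible_sets: none\n")
    return(invisible(x))
  }
  cat(sprintf("credible_sets: %d set(s) at coverage %.2f, min purity %.2f\n",
              length(x), attr(x, "rho"), attr(x, "min_purity")))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.credible_sets <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(cs_id = integer(0), effect = integer(0),
                      coverage = numeric(0), purity = numeric(0),
                      n_snps = integer(0), snps = character(0)))
  data.frame(
    cs_id = seq_along(x),
    effect = vapply(x, `[[`, integer(1), "effect_index"),
    coverage = vapply(x, `[[`, numeric(1), "coverage_attained"),
    purity = vapply(x, `[[`, numeric(1), "purity"),
    n_snps = vapply(x, function(s) length(s$snp_indices), integer(1)),
    snps = vapply(x, function(s) paste(s$snps, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
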