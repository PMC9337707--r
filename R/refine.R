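#' ELBO-guided refinement of a fitted model
#'
#' The coordinate ascent fitter can converge to a poor local optimum of
#' the ELBO, typically when two causal SNPs in moderate LD have partially
#' cancelling effects. This procedure attempts to escape such optima: for
#' each credible set in the current fit, (1) refit from scratch with the
#' set's SNPs excluded (prior weight zero), forcing the model to seek
#' alternative explanations for the observed associations; (2) warm-start
#' a full-SNP fit from that masked solution; (3) accept the candidate only
#' if its ELBO strictly improves on the current fit. Passes repeat until
#' no credible set yields an improvement, so the returned ELBO is always
#' at least as large as the input ELBO.
#'
#' Credible sets are tried in ascending effect-index order within a pass
#' and the best improving candidate is accepted; results can in principle
#' depend on this order.
#'
#' @param fit A `susie_fit` produced by [fit_susie_ss()] on `ss`.
#' @param ss The [suff_stats()] the model was fitted to.
#' @param R LD matrix used to form credible sets.
#' @param rho,min_purity Credible set parameters (defaults 0.95, 0.5).
#' @param max_passes Upper bound on accepted refinement passes
#'   (default 100).
#' @return A `susie_fit` whose final ELBO is `>=` that of `fit`.
#' @export
refine_fit <- function(fit, ss, R, rho = 0.95, min_purity = 0.5,
                       max_passes = 100) {
  if (!inherits(fit, "susie_fit")) fm_stop_input("fit must be a susie_fit")
  st <- fit$settings
  pw <- st$prior_weights
  tol <- st$tol %||% 1e-3   # accepted passes must beat this margin
  elbo_cur <- utils::tail(fit$elbo, 1)

  for (pass in seq_len(max_passes)) {
    css <- collect_credible_sets(fit, R, rho = rho, min_purity = min_purity)
    if (length(css) == 0) break
    best <- NULL
    best_elbo <- elbo_cur
    for (cs in css) {
      pw_masked <- pw
      pw_masked[cs$snp_indices] <- 0
      if (sum(pw_masked) <= 0) next
      masked <- fit_susie_ss(ss, L = st$L, mode = st$mode,
                             fix_sigma2 = st$fix_sigma2,
                             sigma2_init = st$sigma2_init,
                             max_iter = st$max_iter, tol = st$tol,
                             prior_weights = pw_masked,
                             estimate_prior_variance = st$estimate_prior_variance,
                             scaled_prior_variance = st$scaled_prior_variance)
      cand <- fit_susie_ss(ss, L = st$L, mode = st$mode,
                           fix_sigma2 = st$fix_sigma2,
                           sigma2_init = st$sigma2_init,
                           max_iter = st$max_iter, tol = st$tol,
                           prior_weights = pw,
                           estimate_prior_variance = st$estimate_prior_variance,
                           scaled_prior_variance = st$scaled_prior_variance,
                           s_init = list(alpha = masked$alpha, mu1 = masked$mu1,
                                         mu2 = masked$mu2,
                                         prior_vars = masked$prior_vars,
                                         sigma2 = masked$sigma2))
      e <- utils::tail(cand$elbo, 1)
      if (e > best_elbo + tol) {
        best <- cand
        best_elbo <- e
      }
    }
    if (is.null(best)) break
    fit <- best
    elbo_cur <- best_elbo
  }
  fit
}
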