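# finemapss

Bayesian fine-mapping of genetic association signals from summary
statistics, using the **sum of single effects** (SuSiE) regression model
fitted by variational coordinate ascent on sufficient statistics
(IBSS-ss).

Genetic association studies localize signals to regions containing tens
to thousands of SNPs in strong linkage disequilibrium (LD); fine-mapping
narrows each signal to a small *credible set* of candidate causal
variants. Individual-level genotypes are often unavailable, so
`finemapss` works from what studies publish: per-SNP z-scores (or effect
estimates and standard errors) plus an LD matrix from the study itself
or from a reference panel. It is intended for statistical geneticists
running region-level fine-mapping and for methodologists who need a
transparent, fully scriptable implementation with simulation tooling.

## The model

The trait follows a multiple regression `y = Xb + e`,
`e ~ N(0, sigma^2 I)`, with the sparse coefficient vector written as a
sum of *single effects* `b = b_1 + ... + b_L`, each `b_l` nonzero at
exactly one SNP, with a `N(0, sigma0l^2)` effect prior. The likelihood
depends on the data only through the sufficient statistics
`(X'X, X'y, y'y, N)`; for standardized data these are exact functions of
the LD matrix `R`, the PVE-adjusted z-scores
`z~_j = z_j * sqrt(N / (N + z_j^2))`, and `N`:

    X'X = N R,    X'y = sqrt(N) z~,    y'y = N.

Fitting from sufficient statistics (in-sample LD) reproduces
individual-level results exactly; with a reference-panel LD matrix it
approximates them, and the residual variance is then fixed at 1. Each
SNP gets a posterior inclusion probability
`PIP_j = 1 - prod_l (1 - alpha_lj)`, and each non-null effect a 95%
credible set, filtered at purity (minimum absolute within-set LD) 0.5.

The package also provides: an ELBO-guided refinement procedure that
escapes local optima of the coordinate ascent (`refine_fit()`);
maximum-likelihood LD regularization `R_lam = (1-lam) R + lam I`
(`estimate_lambda()`); per-SNP consistency diagnostics and allele-flip
likelihood ratios (`diagnostic_table()`); and a synthetic-data generator
with LD-structured genotypes (`simulate_dataset()`).

## Worked example

Two SNPs with z-scores 6 and 7, in complete LD in the reference panel
(an LD matrix of all ones — singular, and inconsistent with the unequal
z-scores). The model keeps the more significant SNP as the candidate:

```r
library(finemapss)
R <- matrix(1, 2, 2)
fit <- fit_susie_rss(z = c(6, 7), R = R, refine = FALSE)
round(fit$pip, 4)
#> [1] 0.0017 0.9983
collect_credible_sets(fit, R)
#> credible_sets: 1 set(s) at coverage 0.95, min purity 0.50
#>   cs_id effect  coverage purity n_snps snps
#> 1     1      1 0.9982861      1      1 snp2
```

SNP 2 carries PIP 0.9983 and is the sole member of the single credible
set; SNP 1 is effectively excluded (PIP 0.0017) even though the LD
matrix is non-invertible — no pseudoinverse or data transformation is
needed.

A full simulated region (200 SNPs, two causal, in-sample LD):

```r
dat <- simulate_dataset(sim_scenario(seed = 3, n_causal = 2))
ss  <- suff_from_individual(dat$X, dat$y, standardize = TRUE)
fit <- refine_fit(fit_susie_ss(ss, mode = "sufficient"), ss, dat$R_insample)
fit
#> susie_fit: J = 200 SNPs, L = 10 effects (10 non-null), sigma2 = 0.9148
#>   ELBO = -3451.6336 after 4 iteration(s) (converged)
collect_credible_sets(fit, dat$R_insample)
#>   cs_id effect  coverage purity n_snps   snps
#> 1     1      1 1.0000000      1      1  snp10
#> 2     2      2 0.9995231      1      1 snp172
dat$causal_idx
#> [1]  10 172
```

Both credible sets are singletons containing exactly the two true
causal SNPs; `sigma2` estimates the residual variance of the
standardized trait (truth here: 1 minus the simulated 10% PVE).

## Command line

A launcher script ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "finemapss", package = "finemapss"))')" \
  fit --mode summary --summary z.tsv --ld R.txt --n 50000 --out region1
```

Subcommands `fit`, `diagnose`, `simulate`, `estimate-lambda` read/write
tab-separated files and a JSON run manifest; see `--help` on each.

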