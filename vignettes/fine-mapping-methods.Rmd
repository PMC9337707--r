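---
title: "Fine-mapping from summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping from summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapss)
```

## The model

Fine-mapping asks which of $J$ SNPs in an associated region causally
affect a quantitative trait $y$. With individual-level data the standard
model is the multiple linear regression

$$ y = Xb + e, \qquad e \sim N_N(0, \sigma^2 I_N), $$

with $y$ and the columns of $X$ centered. Because causal configurations
are sparse and LD between nearby SNPs is strong, `finemapss` uses the
*sum of single effects* representation

$$ b = \sum_{l=1}^{L} b_l, $$

where each $b_l$ has exactly one nonzero coordinate, drawn
$N(0, \sigma_{0l}^2)$, with a categorical prior $\pi$ (uniform by
default) over which coordinate is nonzero. $L$ is an upper bound on the
number of causal SNPs (default 10); the model is robust to overstating
it, because superfluous effects have their prior variances driven to
zero. The evidence for SNP $j$ is summarized by its posterior inclusion
probability $\mathrm{PIP}_j = \Pr(b_j \neq 0 \mid \text{data})$, and each
non-null effect yields a level-$\rho$ *credible set*: the smallest set of
SNPs covering $\ge \rho$ of that effect's posterior assignment mass.

## Sufficient statistics and the three data regimes

The Gaussian likelihood depends on the data only through
$(X'X,\, X'y,\, y'y,\, N)$. Model fitting from these four quantities
(`fit_susie_ss()`) therefore reproduces individual-level fitting exactly,
at a per-iteration cost of $O(J^2)$ independent of $N$.

When only marginal summary statistics are available, the sufficient
statistics are reconstructed. For standardized $X, y$:

$$ X'X = N R, \qquad X'y = \sqrt{N}\,\tilde z, \qquad y'y = N, $$

where $R$ is the LD (SNP correlation) matrix and
$\tilde z_j = \hat z_j \sqrt{N / (N + \hat z_j^2)}$ are the
*PVE-adjusted* z-scores (`pve_adjusted_z()`): the adjustment factor is
the square root of one minus SNP $j$'s estimated proportion of variance
explained, so it matters only when individual effects are large. On the
effect scale, `suff_from_effect_summary()` inverts the simple-regression
identities to recover $x_j'x_j = y'y / (N\hat s_j^2 + \hat b_j^2)$.

Three regimes follow, selected by an explicit `mode` flag:

| data                          | statistics          | $\sigma^2$            |
|-------------------------------|---------------------|-----------------------|
| individual-level $X, y$       | exact               | estimated             |
| $\hat z$, **in-sample** $R$, $N$ | exact            | estimated             |
| $\hat z$, **panel** $\hat R$, $N$ | approximate     | fixed at $y'y/N$ (=1) |

The residual variance is fixed in the third regime because estimating it
from an approximate $\hat R$ is unreliable. When $N$ is unknown the raw
z-scores stand in for $\tilde z$ (with a warning) and the fit uses
$X'X = R$, $X'y = z$ under a unit-phenotype-variance convention
($y'y/N = 1$, $\sigma^2 = 1$); this is accurate when all effects are
small.

## The single effect regression and IBSS-ss

Conditional on the other effects, updating effect $l$ is a *single
effect regression* on the residual target $X'r_l = X'y - X'X
\sum_{k \neq l} \bar b_k$. Its posterior is closed-form: with
$\hat\beta_j = (X'r_l)_j / d_j$, $s_j^2 = \sigma^2 / d_j$ and
$d = \mathrm{diag}(X'X)$, each SNP gets a normal-means log Bayes factor,
and the assignment probabilities are the prior-weighted softmax of these
(computed with max-shifted exponentials, stable for $|\mathrm{lbf}|$ up
to $10^4$). The SER depends only on the pairs $(x_j'r,\ d_j)$ — never on
off-diagonal LD — so with $L = 1$ the results are invariant to the LD
matrix, including non-invertible ones. Each $\sigma_{0l}^2$ is
re-estimated at every update by maximizing the SER marginal likelihood
over a log-scale interval $[10^{-10}, 10^3] \times y'y/N$ with a bounded
1-D optimizer, with an explicit boundary comparison against
$\sigma_0^2 = 0$ (the null); effects pruned to zero remain revisitable in
later sweeps.

Sweeps visit effects in the fixed order $l = 1..L$ (determinism for
regression tests). The algorithm is coordinate ascent on the evidence
lower bound (ELBO); the trace is recorded per sweep and convergence is
declared when the increase falls below `tol` (default $10^{-3}$).
When $\sigma^2$ is estimated it is updated after each sweep as
$\mathrm{ERSS}/N$, the posterior-expected residual sum of squares over
the sample size. With inconsistent approximate statistics the ERSS can
go non-positive; it is then clamped at $10^{-8}\, y'y$ with a warning
rather than aborting the fit, and the warning is the user's cue to run
the diagnostics below.

## Credible sets, purity, refinement

Credible sets take SNPs in decreasing assignment probability until the
cumulative mass reaches $\rho$ (default 0.95); exact ties break by
ascending SNP index (a convention; any fixed rule works). Each set's
*purity* is the smallest absolute pairwise correlation among its SNPs
(singletons have purity 1; sets above 100 SNPs are subsampled under a
fixed internal seed). Sets with purity below 0.5 are discarded as
uninformative, duplicated index sets collapse to the lowest effect
index, and effects with $\sigma_{0l}^2 = 0$ yield no set.

Coordinate ascent can stall in poor local optima — typically two causal
SNPs in moderate-to-high LD with partially cancelling effects.
`refine_fit()` attacks exactly this geometry: for each credible set,
refit from scratch with the set's SNPs given zero prior weight (masking
by weights rather than subsetting preserves indexing), then warm-start a
full-SNP fit from that solution, and accept only if the ELBO improves by
more than the fitter's `tol`. Passes repeat until stationary (bounded by
`max_passes = 100`); the returned ELBO is never lower than the input's.
Credible sets are tried in ascending effect order and the best improving
candidate per pass is accepted; results can depend on this order in
principle.

## LD regularization and consistency diagnostics

A reference-panel LD estimate $\hat R_0$ differs from the in-sample $R$.
`regularize_ld()` forms $\hat R_\lambda = (1 - \lambda)\hat R_0 +
\lambda I$, and `estimate_lambda()` picks $\lambda$ by maximizing the
null likelihood $N_J(\tilde z; 0, \hat R_\lambda)$ over $[0, 1]$ via one
eigendecomposition ($O(J)$ per objective evaluation afterwards).
Negative eigenvalues of a non-positive-definite panel matrix are
tolerated, but the search interval is restricted so every shifted
eigenvalue exceeds $10^{-10}$ (an unbounded likelihood otherwise); flat
objectives return the smallest maximizer, so $\hat R_0 = I$ gives
$\lambda = 0$. A small $\hat\lambda$ certifies consistency between
z-scores and LD; values past 0.5 signal gross misspecification.

Gross errors — above all *allele flips*, where a SNP is encoded with
opposite alleles in the study and the panel — are localized with the
conditional null distribution $\tilde z_j \mid \tilde z_{-j} \sim
N(-\Omega_{j,-j}\tilde z_{-j} / \Omega_{jj},\ 1/\Omega_{jj})$,
$\Omega = \hat R^{-1}$ (computed for all $j$ from one Cholesky
factorization; a singular $\hat R$ produces an error directing the user
to regularize first). This treats SNP $j$'s own effect as negligible,
which is also why the unadjusted $\hat z$ is acceptable here when $N$ is
unknown. Two statistics follow: the standardized discordance
$t_j = (\tilde z_j - E[\tilde z_j \mid \tilde z_{-j}]) /
\sqrt{1/\Omega_{jj}}$, approximately standard normal under consistency;
and the flip likelihood ratio comparing the sign-negated conditional
mean against the observed one,
$LR_j = \exp(-2 \tilde z_j\, E[\tilde z_j \mid \tilde z_{-j}]\,
\Omega_{jj})$. The LR form is our reading of a sign-flip alternative on
the conditional density; it is validated by its exact antisymmetry
($z_j \to -z_j$ maps $LR_j \to 1/LR_j$) and by simulation (an injected
flip attains the top $|t|$ and top LR among significant SNPs in over 90%
of replicates) rather than against a printed formula.
`diagnostic_table()` assembles everything, ranks SNPs by $|t|$, and
flags $LR > 1$ among SNPs with $|z| > 2$. The cost is one $J \times J$
factorization, so a warning is emitted above $J = 5000$.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws dosages by thresholding two correlated
latent Gaussian "haplotypes" at each SNP's minor allele frequency
(drawn from `maf_range`, default 0.1–0.5), with AR(1) latent correlation
(default 0.95) inside blocks (default 10 SNPs). This reproduces the one
feature summary-data fine-mapping is acutely sensitive to: strong,
block-structured LD, including pairs above $|r| = 0.9$. It does *not*
reproduce rare variants, population structure, imputation dosage error,
or realistic recombination maps — so passing tests certify the
statistical machinery, not robustness to those complications.
`simulate_phenotype()` draws i.i.d. normal causal effects and rescales
them so the realized genetic variance hits the target PVE exactly
against unit residual variance (the target is a *total* PVE, so
per-SNP contributions are exchangeable). `inject_allele_flip()` recodes
one panel SNP as $g \to 2 - g$, exactly negating its panel correlations.

Default study conditions (`sim_scenario()`): $n = 2500$, $J = 200$,
1–3 causal SNPs, total PVE 10%, reference panels of 1000. The
signal-to-noise ($n \times \mathrm{PVE} = 250$) matches biobank-scale
studies of very small effects while remaining computable at desk scale;
the coverage evaluation in the tests and acceptance script uses 200 such
datasets, and the oracle-equivalence checks use $n = 600$, $J = 50$.

## Numerical choices

* Centering and standardization divide by $N$ (population-style
  variance), consistent with the $N$ in the standard-error definition.
* Missing or non-finite per-SNP statistics are rejected, never imputed;
  upstream genotype imputation is assumed. SNPs present in the summary
  file but absent from the LD matrix are an error, not a silent subset.
* Allele labels are carried through but never auto-harmonized —
  harmonization mistakes are precisely what the diagnostics detect.
* Monomorphic SNPs ($d_j = 0$) get Bayes factor 1 and zero posterior
  moments, avoiding 0/0; under `standardize = TRUE` they are a hard
  error naming the SNP.
* The prior-variance optimizer tolerance ($10^{-8}$ on the log scale)
  makes the two-SNP worked example reproducible to four decimals.
* `fit_susie_rss()` without `n` uses the unit-variance convention
  described above; supplying even a rough `n` is preferable.

## Limitations

Binary and case-control phenotypes are handled only through the usual
practice of feeding in their z-scores; no logistic-likelihood theory is
implemented. Meta-analysis summary statistics with per-SNP sample-size
heterogeneity violate the model and should be cleaned upstream. The
diagnostics report inconsistencies once; iterative removal-and-rerun is
left to the user. And the refinement procedure is a heuristic: it
guarantees a no-worse ELBO, not a global optimum.
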