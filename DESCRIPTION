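Package: finemapss
Title: Bayesian Fine-Mapping from Summary Statistics with the Sum of
    Single Effects Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits the sum of single effects (SuSiE) regression model for
    genetic fine-mapping from sufficient statistics (X'X, X'y, y'y, N) or
    from widely available summary data (single-SNP z-scores plus a linkage
    disequilibrium matrix), using the IBSS-ss variational coordinate ascent
    algorithm. Produces posterior inclusion probabilities and purity-filtered
    credible sets, refines fits with an ELBO-guided restart procedure,
    regularizes reference-panel LD matrices with a likelihood-based
    regularization level, and diagnoses inconsistent summary data (expected
    z-scores, discordance statistics, allele-flip likelihood ratios). A
    built-in simulator generates LD-structured genotypes, sparse causal
    effects at a target proportion of variance explained, study summaries,
    reference panels, and injected allele flips.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
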