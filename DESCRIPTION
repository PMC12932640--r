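Package: pqtlmr
Title: Proteome-Wide Cis-pQTL Mendelian Randomization with Pairwise
    Conditional Colocalization
Version: 0.1.0
Authors@R:
    person("pqtlmr", "developers", email = "pqtlmr@example.org",
           role = c("aut", "cre"))
Description: Tools for screening circulating proteins for causal effects on
    disease outcomes using cis protein quantitative trait loci (cis-pQTLs)
    as genetic instruments. Implements instrument selection (cis window,
    minor allele frequency and protein-altering filters, palindromic-SNP
    removal, allele harmonization, LD pruning), Wald-ratio and
    inverse-variance-weighted Mendelian randomization with Cochran's Q
    driven fixed/random-effects choice, approximate-Bayes-factor
    colocalization posteriors, approximate conditional/joint association
    analysis from summary statistics with a reference LD panel, and
    pairwise conditional colocalization over all combinations of
    conditional and unconditional datasets. Includes a locus-scale GWAS
    summary-statistics simulator (AR(1) latent-Gaussian haplotypes,
    liability-threshold binary outcomes) so that every stage of the
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
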