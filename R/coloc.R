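# Approximate-Bayes-factor colocalization for a pair of traits.
#
# Per-SNP Wakefield log ABFs are combined, entirely in log space, into
# posterior probabilities of the five hypotheses: H0 no association, H1/H2
# association with one trait only, H3 two distinct causal variants, H4 one
# shared causal variant.

#' Per-SNP approximate Bayes factors
#'
#' For each SNP with z = beta/se and V = se^2, with prior effect variance
#' `W = prior_sd^2` and shrinkage `r = W/(W+V)`, the log ABF is
#' `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Aligned effect and SE vectors (se > 0).
#' @param trait_type `"quantitative"` or `"binary"`; chooses the default
#'   prior effect SD (0.15 per-SD scale, 0.2 log-odds scale).
#' @param prior_sd Override the prior effect SD.
#' @param snp_id Optional SNP identifiers attached to the result.
#' @return data.frame with `snp_id`, `z`, `V`, `r_abf`, `log_abf`.
#' @export
abf <- function(beta, se, trait_type = c("quantitative", "binary"),
                prior_sd = NULL, snp_id = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(length(beta) == length(se), all(se > 0))
  W <- (prior_sd %||% switch(trait_type, quantitative = 0.15, binary = 0.2))^2
  z <- beta / se
  V <- se^2
  r <- W / (W + V)
  data.frame(snp_id = snp_id %||% paste0("snp", seq_along(beta)),
             z = z, V = V, r_abf = r,
             log_abf = 0.5 * (log1p(-r) + r * z^2),
             stringsAsFactors = FALSE)
}

#' Colocalization priors
#'
#' @param p1,p2 Per-SNP prior probability of association with trait 1 / 2
#'   (default 1e-4, the conventional defaults).
#' @param p12 Per-SNP prior probability of association with both traits
#'   (default 1e-5).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= p1, p12 <= p2, p1 < 1, p2 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Colocalization posterior probabilities for two aligned ABF vectors
#'
#' With `S1 = sum_j ABF1_j`, `S2 = sum_j ABF2_j` and
#' `S12 = sum_j ABF1_j * ABF2_j` (all accumulated with log-sum-exp), the
#' unnormalized hypothesis weights are `L0 = 1`, `L1 = p1 S1`,
#' `L2 = p2 S2`, `L3 = p1 p2 (S1 S2 - S12)` (clamped at >= 0) and
#' `L4 = p12 S12`; posteriors are `L_h / sum(L)`.
#'
#' @param abf1,abf2 [abf()] outputs aligned on identical SNP lists.
#' @param priors A [coloc_priors()].
#' @param label Dataset-combination label carried on the result.
#' @return A `coloc_posterior`: pp0..pp4, n_snps, priors, label.
#' @export
coloc_posteriors <- function(abf1, abf2, priors = coloc_priors(),
                             label = "unconditional/unconditional") {
  if (nrow(abf1) == 0L || nrow(abf2) == 0L) {
    stop("empty SNP set for colocalization")
  }
  if (nrow(abf1) != nrow(abf2) ||
      !identical(abf1$snp_id, abf2$snp_id)) {
    stop("abf vectors are not aligned on the same SNP list")
  }
  l1 <- abf1$log_abf
  l2 <- abf2$log_abf
  logS1 <- logsumexp(l1)
  logS2 <- logsumexp(l2)
  logS12 <- logsumexp(l1 + l2)
  logL <- c(h0 = 0,
            h1 = log(priors$p1) + logS1,
            h2 = log(priors$p2) + logS2,
            h3 = log(priors$p1) + log(priors$p2) +
              logdiffexp(logS1 + logS2, logS12),
            h4 = log(priors$p12) + logS12)
  pp <- exp(logL - logsumexp(logL))
  pp <- pp / sum(pp)
  structure(list(pp0 = unname(pp[1]), pp1 = unname(pp[2]),
                 pp2 = unname(pp[3]), pp3 = unname(pp[4]),
                 pp4 = unname(pp[5]),
                 n_snps = nrow(abf1), priors = priors, label = label),
            class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf("coloc_posterior [%s], %d SNP(s):\n", x$label, x$n_snps))
  cat(sprintf("  PP.H0-H4: %.4f %.4f %.4f %.4f %.4f\n",
              x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  invisible(x)
}

#' Colocalize two summary-statistics datasets over their shared SNPs
#'
#' Convenience wrapper: intersects the SNP lists of two aligned
#' beta/se data sources (sumstat tables or conditional datasets), computes
#' per-trait ABFs and returns the posterior.  Both inputs are assumed to
#' already share allele orientation (harmonize upstream).
#'
#' @param d1,d2 Objects with `snp_id`, `beta`, `se` columns (a
#'   [sumstat_table()] or the `records` of a conditional dataset).
#' @param trait_type1,trait_type2 Trait types for the prior effect SDs.
#' @param priors A [coloc_priors()].
#' @param prior_sd1,prior_sd2 Optional per-trait prior SD overrides.
#' @param label Combination label.
#' @return A `coloc_posterior`.
#' @export
coloc_datasets <- function(d1, d2,
                           trait_type1 = "quantitative",
                           trait_type2 = "quantitative",
                           priors = coloc_priors(),
                           prior_sd1 = NULL, prior_sd2 = NULL,
                           label = "unconditional/unconditional") {
  d1 <- as.data.frame(d1); d2 <- as.data.frame(d2)
  shared <- intersect(d1$snp_id, d2$snp_id)
  if (length(shared) == 0L) stop("no shared SNPs between datasets")
  i1 <- match(shared, d1$snp_id); i2 <- match(shared, d2$snp_id)
  a1 <- abf(d1$beta[i1], d1$se[i1], trait_type1, prior_sd1, snp_id = shared)
  a2 <- abf(d2$beta[i2], d2$se[i2], trait_type2, prior_sd2, snp_id = shared)
  coloc_posteriors(a1, a2, priors, label = label)
}
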