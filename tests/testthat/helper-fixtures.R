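# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no stored data.

# Minimal well-formed summary-statistics data.frame.
make_sumstat_df <- function(n = 3L, snp_id = sprintf("rs%d", seq_len(n)),
                            beta = seq(0.1, by = 0.1, length.out = n),
                            se = rep(0.05, n),
                            eaf = rep(0.3, n),
                            ea = rep("A", n), oa = rep("G", n),
                            pos = seq(1000L, by = 1000L, length.out = n)) {
  data.frame(snp_id = snp_id, chrom = rep("1", n), pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             pvalue = pmin(1, 2 * pnorm(-abs(beta / se))),
             n = rep(1000, n), stringsAsFactors = FALSE)
}

# Two-SNP panel sampled from explicit haplotype frequencies
# (h = c(AB, Ab, aB, ab)); counted alleles are "A" at both loci.
panel_from_haplotypes <- function(h, n, seed = 1) {
  stopifnot(abs(sum(h) - 1) < 1e-12)
  set.seed(seed)
  hap <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
  draw <- function() hap[sample(4, n, replace = TRUE, prob = h), , drop = FALSE]
  d <- draw() + draw()
  colnames(d) <- c("rsA", "rsB")
  genotype_panel(d, data.frame(snp_id = c("rsA", "rsB"),
                               counted_allele = "A", other_allele = "G",
                               stringsAsFactors = FALSE))
}

# Independent per-SNP least-squares oracle computed with lm(), one SNP at
# a time; returns a sumstat_table.  Used as the route-independent source
# of "published" marginal statistics for COJO oracle tests.
sumstats_from_xy_lm <- function(X, y, trait_id = "trait") {
  m <- ncol(X)
  rows <- lapply(seq_len(m), function(j) {
    fit <- summary(lm(y ~ X[, j]))$coefficients
    data.frame(snp_id = colnames(X)[j], chrom = "1", pos = j * 1000L,
               effect_allele = "A", other_allele = "G",
               eaf = mean(X[, j]) / 2,
               beta = fit[2, 1], se = fit[2, 2],
               pvalue = max(fit[2, 4], 1e-300), n = nrow(X),
               stringsAsFactors = FALSE)
  })
  sumstat_table(do.call(rbind, rows), trait_id = trait_id, quiet = TRUE)
}

# Small locus-pair configuration used across tests.
small_config <- function(...) {
  defaults <- list(m_snps = 40L, n_exposure = 2000L, n_outcome = 3000L,
                   n_ref = 500L, ld_rho = 0.8,
                   exposure_causals = list(c(20L, 0.25)),
                   outcome_architecture = "shared", theta = 0.4, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  if (!("exposure_causals" %in% names(list(...)))) {
    idx <- min(20L, max(1L, args$m_snps %/% 2L))
    args$exposure_causals <- list(c(idx, 0.25))
  }
  do.call(sim_config, args)
}
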