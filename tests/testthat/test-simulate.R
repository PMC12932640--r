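# synthetic_data: genotype and summary-statistics generator.

test_that("simulated MAF and LD match their targets", {
  cfg <- sim_config(m_snps = 10L, maf_range = c(0.3, 0.3), ld_rho = 0,
                    n_ref = 10000L, n_exposure = 50L, n_outcome = 50L,
                    exposure_causals = list(c(1L, 0.1)), seed = 5L)
  panel <- simulate_genotypes(cfg, "reference")
  maf <- colMeans(panel$dosages) / 2
  expect_true(all(abs(maf - 0.3) < 0.02))

  # ld_rho = 0: average inter-SNP r^2 below 2/n_ref
  R <- ld_matrix(panel)
  r2 <- R[upper.tri(R)]^2
  expect_lt(mean(r2), 2 / 10000)
})

test_that("adjacent-SNP haplotypic correlation matches the latent-threshold analytic value", {
  rho <- 0.95; maf <- 0.3
  # analytic oracle: P(Z1 < t, Z2 < t) under bivariate normal with corr rho,
  # by one-dimensional quadrature
  t <- qnorm(maf)
  p11 <- integrate(function(z) {
    pnorm((t - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
  }, -Inf, t)$value
  r_analytic <- (p11 - maf^2) / (maf * (1 - maf))

  set.seed(1234)
  H <- pqtlmr:::.sim_haplotypes(20000L, c(maf, maf), rho)
  r_emp <- cor(H[, 1], H[, 2])
  expect_equal(r_emp, r_analytic, tolerance = 0.05)
})

test_that("null architecture gives calibrated outcome p-values and null exposure gives z^2 ~ 1", {
  # pool outcome p-values over replicated small null loci (>= 5000 SNPs)
  pvals <- unlist(lapply(1:25, function(i) {
    cfg <- sim_config(m_snps = 200L, ld_rho = 0, n_exposure = 50L,
                      n_outcome = 400L, n_ref = 50L,
                      exposure_causals = list(c(1L, 0.2)),
                      outcome_architecture = "null", seed = 1000L + i)
    simulate_locus_pair(cfg)$outcome$pvalue
  }))
  expect_gte(length(pvals), 5000L)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.01)

  # exposure causal with effect 0 -> mean z^2 ~ 1
  cfg <- sim_config(m_snps = 300L, ld_rho = 0, n_exposure = 1500L,
                    n_outcome = 50L, n_ref = 50L,
                    exposure_causals = list(c(1L, 0)),
                    outcome_architecture = "null", seed = 77L)
  lp <- simulate_locus_pair(cfg)
  z2 <- (lp$exposure$beta / lp$exposure$se)^2
  expect_equal(mean(z2), 1, tolerance = 0.2)
})

test_that("shared architecture puts the minimum p at the causal SNP in both traits", {
  hits <- vapply(1:10, function(i) {
    cfg <- sim_config(m_snps = 30L, ld_rho = 0.5, n_exposure = 4000L,
                      n_outcome = 4000L, n_ref = 50L,
                      exposure_causals = list(c(15L, 0.25)),
                      outcome_architecture = "shared", theta = 1,
                      seed = 2000L + i)
    lp <- simulate_locus_pair(cfg)
    which.min(lp$exposure$pvalue) == 15L && which.min(lp$outcome$pvalue) == 15L
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("SE scales as 1/sqrt(n) and LD proxies attenuate by r", {
  base <- small_config(seed = 31L)
  lp1 <- simulate_locus_pair(base)
  big <- small_config(seed = 31L, n_exposure = 8000L)
  lp2 <- simulate_locus_pair(big)
  ratio <- median(lp2$exposure$se) / median(lp1$exposure$se)
  expect_equal(ratio, sqrt(2000 / 8000), tolerance = 0.1)

  # marginal standardized beta of a proxy ~ r * causal standardized beta
  cfg <- small_config(seed = 32L, n_exposure = 8000L, n_ref = 4000L,
                      exposure_causals = list(c(20L, 0.3)))
  lp <- simulate_locus_pair(cfg)
  r <- ld_r(lp$panel, "rs20", "rs21")
  std_beta <- function(tab, id) {
    i <- match(id, tab$snp_id)
    tab$beta[i] * sqrt(2 * tab$eaf[i] * (1 - tab$eaf[i]))
  }
  expect_equal(std_beta(lp$exposure, "rs21"),
               r * std_beta(lp$exposure, "rs20"), tolerance = 0.04)
})

test_that("cohorts are independent draws and the proteome is deterministic", {
  cfg <- small_config(seed = 9L, m_snps = 4L, n_exposure = 3000L,
                      n_outcome = 3000L, n_ref = 3000L)
  pe <- simulate_genotypes(cfg, "exposure")
  po <- simulate_genotypes(cfg, "outcome")
  pr <- simulate_genotypes(cfg, "reference")
  # same process, different draws
  expect_false(identical(pe$dosages[1:100, ], po$dosages[1:100, ]))
  expect_false(identical(pe$dosages[1:100, ], pr$dosages[1:100, ]))
  expect_lt(abs(cor(pe$dosages[1:3000, 1], po$dosages[1:3000, 1])), 0.06)

  base <- small_config(m_snps = 20L, n_exposure = 300L, n_outcome = 300L,
                       n_ref = 100L)
  s1 <- simulate_proteome(4, causal = c(2, 3), base_config = base, seed = 77L)
  s2 <- simulate_proteome(4, causal = c(2, 3), base_config = base, seed = 77L)
  expect_identical(s1, s2)
  expect_identical(s1$truth$causal, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(names(s1$proteins), s1$truth$protein_id)
})

test_that("binary outcomes use the liability threshold and log-odds scale", {
  cfg <- small_config(seed = 13L, outcome_type = "binary",
                      case_fraction = 0.2, n_outcome = 6000L,
                      outcome_architecture = "shared", theta = 0.5)
  lp <- simulate_locus_pair(cfg)
  expect_identical(attr(lp$outcome, "trait_type"), "binary")
  # strongest signal at the causal SNP, positive log-odds for a
  # risk-increasing exposure effect
  i <- which.min(lp$outcome$pvalue)
  expect_equal(lp$outcome$snp_id[i], "rs20")
  expect_gt(lp$outcome$beta[i], 0)

  # same liability, quantitative vs binary: concordant effect signs
  cfg_q <- small_config(seed = 13L, outcome_architecture = "shared",
                        theta = 0.5)
  lp_q <- simulate_locus_pair(cfg_q)
  expect_gt(sign(lp_q$outcome$beta[20]) * sign(lp$outcome$beta[20]), 0)
})
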