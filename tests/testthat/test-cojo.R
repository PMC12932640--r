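# conditional_cojo: joint/conditional estimates from summary statistics,
# validated against individual-level least squares.

# Individual-level fixture: genotypes with LD, linear phenotype, marginal
# sumstats computed per SNP by lm() (the independent oracle route), and a
# workspace whose reference panel IS the GWAS cohort.
make_cojo_fixture <- function(n = 3000, m = 12, rho = 0.7,
                              causal = c(4, 9), effects = c(0.25, 0.2),
                              seed = 101) {
  set.seed(seed)
  mafs <- runif(m, 0.15, 0.45)
  H <- pqtlmr:::.sim_haplotypes(2L * n, mafs, rho)
  X <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  colnames(X) <- paste0("rs", seq_len(m))
  b <- numeric(m); b[causal] <- effects
  y <- as.vector(scale(X) %*% b) + rnorm(n, 0, sqrt(1 - sum(b^2)))
  sumstats <- sumstats_from_xy_lm(X, y, "trait")
  panel <- genotype_panel(X, data.frame(snp_id = colnames(X),
                                        counted_allele = "A",
                                        other_allele = "G"))
  list(X = X, y = y, sumstats = sumstats, panel = panel,
       ws = cojo_workspace(sumstats, panel))
}

test_that("single-SNP joint fit reduces to the marginal statistics", {
  fx <- make_cojo_fixture()
  jf <- joint_fit(fx$ws, "rs4")
  i <- match("rs4", fx$sumstats$snp_id)
  expect_equal(jf$beta, fx$sumstats$beta[i], tolerance = 0.01)
  expect_equal(jf$se, fx$sumstats$se[i], tolerance = 0.02)
})

test_that("joint and conditional estimates match multiple least squares within 1%", {
  fx <- make_cojo_fixture()
  snps <- c("rs4", "rs9")
  jf <- joint_fit(fx$ws, snps)
  oracle <- summary(lm(fx$y ~ fx$X[, "rs4"] + fx$X[, "rs9"]))$coefficients
  expect_equal(jf$beta, unname(oracle[2:3, 1]), tolerance = 0.01)
  expect_equal(jf$se, unname(oracle[2:3, 2]), tolerance = 0.01)

  # conditional stats of a third SNP given rs4: partial-regression oracle
  cs <- conditional_stats(fx$ws, "rs4")
  orc <- summary(lm(fx$y ~ fx$X[, "rs4"] + fx$X[, "rs9"]))$coefficients
  row9 <- cs$records[cs$records$snp_id == "rs9", ]
  expect_equal(row9$beta, unname(orc[3, 1]), tolerance = 0.01)
  expect_equal(row9$se, unname(orc[3, 2]), tolerance = 0.01)
  # conditioning SNPs are absent from the reported records
  expect_false("rs4" %in% cs$records$snp_id)
})

test_that("orthogonal SNPs leave each other's estimates unchanged", {
  fx <- make_cojo_fixture(rho = 0, seed = 202)
  jf <- joint_fit(fx$ws, c("rs4", "rs9"))
  i <- match(c("rs4", "rs9"), fx$sumstats$snp_id)
  expect_equal(jf$beta, fx$sumstats$beta[i], tolerance = 0.03)
  # empty conditioning set returns marginals exactly
  cs <- conditional_stats(fx$ws, character(0))
  expect_equal(cs$records$beta, fx$sumstats$beta, tolerance = 1e-12)
})

test_that("a proxy's signal vanishes when conditioning on the causal SNP", {
  # rho high so rs5 (causal) and rs6 (proxy) are strongly correlated
  fx <- make_cojo_fixture(n = 5000, m = 10, rho = 0.95, causal = 5,
                          effects = 0.25, seed = 303)
  r2 <- ld_r2(fx$panel, "rs5", "rs6")
  expect_gt(r2, 0.5)
  marg_z <- abs(fx$sumstats$beta[6] / fx$sumstats$se[6])
  expect_gt(marg_z, 8)
  ca <- conditional_association(fx$ws, "rs6", "rs5")
  expect_lt(abs(ca$beta / ca$se), 2)
  # conditioning on an uncorrelated SNP changes little
  ca2 <- conditional_association(fx$ws, "rs6", "rs1")
  expect_equal(ca2$beta, fx$sumstats$beta[6], tolerance = 0.1)
  # empty conditioning set returns the marginal
  ca3 <- conditional_association(fx$ws, "rs6")
  expect_equal(ca3$beta, fx$sumstats$beta[6])
})

test_that("collinear SNPs are flagged, not fit", {
  fx <- make_cojo_fixture()
  X2 <- cbind(fx$X, dup = fx$X[, "rs4"])
  colnames(X2)[ncol(X2)] <- "rs_dup"
  ss <- sumstats_from_xy_lm(X2, fx$y)
  panel <- genotype_panel(X2, data.frame(snp_id = colnames(X2),
                                         counted_allele = "A",
                                         other_allele = "G"))
  ws <- cojo_workspace(ss, panel)
  cs <- conditional_stats(ws, "rs4")
  dup_row <- cs$records[cs$records$snp_id == "rs_dup", ]
  expect_true(dup_row$collinear)
  expect_equal(dup_row$beta, 0)
  expect_error(joint_fit(ws, c("rs4", "rs_dup")), "collinear")
})

test_that("stepwise selection finds the independent signals and is order invariant", {
  fx <- make_cojo_fixture(n = 6000, m = 20, rho = 0.6,
                          causal = c(5, 15), effects = c(0.22, 0.2),
                          seed = 404)
  sel <- stepwise_select(fx$ws, p_cutoff = 5e-8)
  expect_setequal(sel, c("rs15", "rs5"))
  # selected set never contains a collinear pair
  R <- ld_matrix(fx$panel, sel)
  expect_lte(max(R[upper.tri(R)]^2), fx$ws$collinearity_r2)

  # input-order invariance: shuffle the sumstat rows
  df <- as.data.frame(fx$sumstats)
  set.seed(1); df <- df[sample(nrow(df)), ]
  ws2 <- cojo_workspace(sumstat_table(df, quiet = TRUE), fx$panel)
  expect_identical(stepwise_select(ws2, p_cutoff = 5e-8), sel)

  # no signal below the cutoff -> empty selection
  expect_identical(stepwise_select(fx$ws, p_cutoff = 1e-300), character(0))
})

test_that("workspace flags frequency mismatches and handles allele flips", {
  fx <- make_cojo_fixture(m = 6, causal = c(2, 4), effects = c(0.25, 0.2),
                          seed = 505)
  df <- as.data.frame(fx$sumstats)
  # flip the reported allele of rs2: panel column must be reflected
  i <- df$snp_id == "rs2"
  df[i, c("effect_allele", "other_allele")] <- c("G", "A")
  df$beta[i] <- -df$beta[i]
  df$eaf[i] <- 1 - df$eaf[i]
  ws2 <- cojo_workspace(sumstat_table(df, quiet = TRUE), fx$panel)
  jf1 <- joint_fit(fx$ws, c("rs2", "rs4"))
  jf2 <- joint_fit(ws2, c("rs2", "rs4"))
  expect_equal(abs(jf1$beta), abs(jf2$beta), tolerance = 1e-10)

  df$eaf[df$snp_id == "rs3"] <- 0.95  # gross frequency mismatch
  expect_warning(cojo_workspace(sumstat_table(df, quiet = TRUE), fx$panel),
                 "panel freq")
})
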