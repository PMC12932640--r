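# instruments: selection filters, palindromic handling, harmonization,
# LD pruning.

make_annot <- function(snp_id, gene = "GENE1", tss = 1000L, altering = FALSE) {
  variant_annotation(data.frame(snp_id = snp_id, gene = gene, tss_pos = tss,
                                protein_altering = altering))
}

test_that("select_cis_pqtls applies every filter with a reason code", {
  exp_df <- make_sumstat_df(6, beta = rep(0.5, 6), se = rep(0.02, 6))
  exp_df$eaf <- c(0.3, 0.005, 0.3, 0.3, 0.3, 0.3)       # rs2: MAF 0.5%
  exp_df$pvalue <- c(1e-20, 1e-20, 1e-3, 1e-20, 1e-20, 1e-20)  # rs3: weak
  exp_df$pos[5] <- 5e6                                   # rs5: outside cis
  exposure <- sumstat_table(exp_df, "prot", quiet = TRUE)
  outcome <- sumstat_table(make_sumstat_df(6)[-6, ], "out", quiet = TRUE) # rs6 absent
  annot <- make_annot(exp_df$snp_id, altering = c(rep(FALSE, 3), TRUE,
                                                  FALSE, FALSE))  # rs4 altering
  sel <- select_cis_pqtls(exposure, annot, outcome, "GENE1")
  expect_identical(sel$candidates$snp_id, "rs1")
  got <- setNames(sel$exclusions$reason, sel$exclusions$snp_id)
  expect_identical(got[["rs2"]], "maf")
  expect_identical(got[["rs3"]], "pvalue")
  expect_identical(got[["rs4"]], "protein_altering")
  expect_identical(got[["rs5"]], "cis_window")
  expect_identical(got[["rs6"]], "not_in_outcome")
  expect_error(select_cis_pqtls(exposure, annot, outcome, "NOPE"),
               "gene not present")
})

test_that("palindromic SNPs are removed only in the ambiguous frequency band", {
  df <- make_sumstat_df(3, ea = c("A", "A", "A"), oa = c("T", "T", "G"),
                        eaf = c(0.50, 0.10, 0.50))
  res <- remove_palindromic(df)
  expect_identical(res$exclusions$snp_id, "rs1")
  expect_identical(res$exclusions$reason, "palindromic_ambiguous_freq")
  expect_identical(res$candidates$snp_id, c("rs2", "rs3"))
  expect_identical(res$candidates$palindromic, c(TRUE, FALSE))
  # band endpoints are inclusive
  df2 <- make_sumstat_df(2, ea = c("C", "C"), oa = c("G", "G"),
                         eaf = c(0.45, 0.55))
  expect_equal(nrow(remove_palindromic(df2)$candidates), 0L)
})

test_that("harmonization covers swapped, strand-flipped and palindromic orientations", {
  cand <- make_sumstat_df(5, ea = c("A", "A", "A", "A", "A"),
                          oa = c("G", "G", "G", "G", "T"),
                          beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
                          eaf = c(0.3, 0.3, 0.3, 0.3, 0.10))
  out_df <- make_sumstat_df(5)
  out_df$beta <- rep(0.05, 5)
  # rs1 direct; rs2 swapped; rs3 strand-flip; rs4 mismatch; rs5 palindromic
  out_df$effect_allele <- c("A", "G", "T", "A", "A")
  out_df$other_allele  <- c("G", "A", "C", "C", "T")
  out_df$eaf <- c(0.3, 0.7, 0.3, 0.3, 0.88)
  outcome <- sumstat_table(out_df, "out", quiet = TRUE)
  h <- harmonize(cand, outcome)
  expect_setequal(h$instruments$snp_id, c("rs1", "rs2", "rs3", "rs5"))
  g <- function(id, col) h$instruments[h$instruments$snp_id == id, col]
  expect_equal(g("rs1", "beta_out"), 0.05)
  expect_equal(g("rs2", "beta_out"), -0.05)   # allele swap -> sign flip
  expect_equal(g("rs2", "eaf_out"), 0.3)
  expect_equal(g("rs3", "beta_out"), 0.05)    # strand flip, same orientation
  # retained palindromic, frequency sides disagree (0.10 vs 0.88) -> flipped
  expect_equal(g("rs5", "beta_out"), -0.05)
  expect_equal(g("rs5", "eaf_out"), 0.12)
  expect_identical(h$exclusions$reason, "allele_mismatch")

  # every input appears exactly once across retained + excluded
  expect_setequal(c(h$instruments$snp_id, h$exclusions$snp_id), cand$snp_id)
})

test_that("harmonization is involutive under outcome allele-label swaps", {
  cand <- make_sumstat_df(4, ea = c("A", "C", "G", "T"),
                          oa = c("G", "A", "C", "G"), eaf = rep(0.25, 4))
  out_df <- cand
  out_df$beta <- c(0.2, -0.1, 0.05, 0.3)
  h1 <- harmonize(cand, sumstat_table(out_df, "o", quiet = TRUE))
  swapped <- out_df
  swapped$effect_allele <- out_df$other_allele
  swapped$other_allele <- out_df$effect_allele
  swapped$beta <- -out_df$beta
  swapped$eaf <- 1 - out_df$eaf
  h2 <- harmonize(cand, sumstat_table(swapped, "o", quiet = TRUE))
  expect_equal(h1$instruments, h2$instruments)
})

test_that("ld_prune is greedy on significance and enforces the r2 ceiling", {
  # chain A-B r2 = 0.5, B-C r2 = 0.5, A-C r2 ~ 0 with p(A) < p(B) < p(C):
  # expect {A, C}
  set.seed(42)
  n <- 4000
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.72, a, rbinom(n, 2, 0.4))   # corr(a,b)^2 ~ 0.5
  cc <- rbinom(n, 2, 0.4)
  cc2 <- ifelse(runif(n) < 0.72, cc, rbinom(n, 2, 0.4))
  d <- cbind(A = a, B = b, C = cc2, C0 = cc)
  panel <- genotype_panel(d, data.frame(snp_id = colnames(d),
                                        counted_allele = "A",
                                        other_allele = "G"))
  r2ab <- ld_r2(panel, "A", "B")
  expect_gt(r2ab, 0.3)
  inst <- data.frame(snp_id = c("A", "B", "C0"),
                     effect_allele = "A", other_allele = "G",
                     beta_exp = c(0.5, 0.4, 0.3), se_exp = 0.02,
                     p_exp = c(1e-20, 1e-12, 1e-8), eaf_exp = 0.4,
                     beta_out = 0.1, se_out = 0.05, p_out = 0.1,
                     eaf_out = 0.4, n_exp = n, n_out = n,
                     palindromic = FALSE, stringsAsFactors = FALSE)
  set1 <- ld_prune(inst, panel, r2_threshold = 0.01)
  expect_setequal(set1$instruments$snp_id, c("A", "C0"))
  expect_identical(set1$exclusions$reason, "ld_prune")

  # duplicate columns: the most significant is kept
  d2 <- cbind(X = a, Y = a)
  p2 <- genotype_panel(d2, data.frame(snp_id = c("X", "Y"),
                                      counted_allele = "A",
                                      other_allele = "G"))
  inst2 <- inst[1:2, ]; inst2$snp_id <- c("Y", "X")
  inst2$p_exp <- c(1e-8, 1e-20)
  set2 <- ld_prune(inst2, p2)
  expect_identical(set2$instruments$snp_id, "X")

  # no-op when all pairwise r2 <= threshold; max pairwise r2 invariant
  inst3 <- inst; inst3$snp_id <- c("A", "C0", "C")
  set3 <- ld_prune(inst3[c(1, 2), ], panel)
  expect_equal(nrow(set3$instruments), 2L)
  R <- ld_matrix(panel, set3$instruments$snp_id)
  expect_lte(max(R[upper.tri(R)]^2), 0.01)

  expect_error(ld_prune(inst, p2), "absent from reference panel")
})

test_that("select_instruments partitions every exposure SNP across retained and excluded", {
  cfg <- small_config(seed = 21L)
  lp <- simulate_locus_pair(cfg)
  iset <- select_instruments(lp$exposure, lp$annotation, lp$outcome,
                             lp$panel, gene = "GENE1")
  expect_setequal(c(iset$instruments$snp_id, iset$exclusions$snp_id),
                  lp$exposure$snp_id)
  expect_gte(nrow(iset$instruments), 1L)
  if (nrow(iset$instruments) > 1L) {
    R <- ld_matrix(lp$panel, iset$instruments$snp_id)
    expect_lte(max(R[upper.tri(R)]^2), 0.01)
  }
})
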