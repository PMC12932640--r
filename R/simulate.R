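# Locus-scale GWAS summary-statistics simulator.
#
# Haplotypes are drawn from a latent Gaussian AR(1) process thresholded at
# per-SNP MAF quantiles, which yields a tunable decaying-LD block without a
# coalescent simulator.  Exposure and outcome cohorts and the reference
# panel are independent draws from the same process (the two-sample MR
# assumption), driven by named sub-streams of one master seed.

#' Simulation configuration for one locus pair
#'
#' Default sizes are desk scale (`m_snps = 200`, `n_exposure = 5000`,
#' `n_outcome = 20000`, `n_ref = 2000`); real proteome GWAS are far larger,
#' so default effect sizes are inflated correspondingly to reach the
#' power regimes of interest (a standardized effect b gives |z| ~ b*sqrt(n)).
#'
#' @param m_snps Number of SNPs in the locus.
#' @param maf_range Range for per-SNP minor-allele frequencies, in (0, 0.5].
#' @param ld_rho AR(1) correlation of the latent Gaussian, in `[0, 1)`.
#' @param n_exposure,n_outcome,n_ref Cohort sizes (each >= 50).
#' @param exposure_causals List of `c(index, effect)` pairs; effects are in
#'   SD units of the standardized dosage.
#' @param outcome_architecture One of `"shared"`, `"distinct"`, `"null"`,
#'   `"two_signal_one_shared"`.
#' @param theta Causal effect of the exposure on the outcome liability
#'   (used by the `"shared"` architecture).
#' @param outcome_causals Optional list of `c(index, effect)` pairs giving
#'   direct outcome effects; defaults are derived from the architecture.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @param case_fraction Case fraction for binary outcomes (liability
#'   threshold model).
#' @param binary_model `"logistic_score"` (default; log-odds scale) or
#'   `"linear"` (linear-probability OLS, for exact least-squares oracles).
#' @param chrom,locus_start,snp_spacing Coordinates assigned to the SNPs.
#' @param snp_prefix Prefix for generated SNP identifiers.
#' @param seed Master seed; named sub-streams for MAF/alleles, each cohort
#'   and each phenotype are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(m_snps = 200L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.9,
                       n_exposure = 5000L,
                       n_outcome = 20000L,
                       n_ref = 2000L,
                       exposure_causals = list(c(100L, 0.17)),
                       outcome_architecture = c("shared", "distinct", "null",
                                                "two_signal_one_shared"),
                       theta = 0.3,
                       outcome_causals = NULL,
                       outcome_type = c("quantitative", "binary"),
                       case_fraction = 0.1,
                       binary_model = c("logistic_score", "linear"),
                       chrom = "1", locus_start = 1e6L, snp_spacing = 5000L,
                       snp_prefix = "rs",
                       seed = 1L) {
  outcome_architecture <- match.arg(outcome_architecture)
  outcome_type <- match.arg(outcome_type)
  binary_model <- match.arg(binary_model)
  stopifnot(m_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1,
            n_exposure >= 50, n_outcome >= 50, n_ref >= 50,
            theta >= -5, theta <= 5,
            case_fraction > 0, case_fraction < 1)
  norm_causals <- function(x) {
    if (is.matrix(x)) x <- asplit(x, 1)          # row-per-causal input
    if (is.numeric(x) && length(x) == 2) x <- list(x)
    lapply(x, function(ce) {
      ce <- as.numeric(ce)
      if (length(ce) != 2) stop("each causal must be c(index, effect)")
      if (ce[1] < 1 || ce[1] > m_snps) stop("causal index out of range")
      list(index = as.integer(ce[1]), effect = ce[2])
    })
  }
  exposure_causals <- norm_causals(exposure_causals)
  if (outcome_architecture == "two_signal_one_shared" &&
      length(exposure_causals) < 2) {
    stop("two_signal_one_shared requires >= 2 exposure causals")
  }
  if (outcome_architecture == "distinct" && m_snps < 2) {
    stop("distinct architecture requires m_snps >= 2")
  }
  if (!is.null(outcome_causals)) outcome_causals <- norm_causals(outcome_causals)
  structure(list(m_snps = as.integer(m_snps), maf_range = maf_range,
                 ld_rho = ld_rho,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 n_ref = as.integer(n_ref),
                 exposure_causals = exposure_causals,
                 outcome_architecture = outcome_architecture,
                 theta = theta, outcome_causals = outcome_causals,
                 outcome_type = outcome_type,
                 case_fraction = case_fraction, binary_model = binary_model,
                 chrom = as.character(chrom),
                 locus_start = as.integer(locus_start),
                 snp_spacing = as.integer(snp_spacing),
                 snp_prefix = snp_prefix,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Locus-level invariants shared by all cohorts: MAFs, allele labels,
# positions.  Deterministic under the "maf" sub-stream.
.locus_layout <- function(config) {
  set.seed(derive_seed(config$seed, "maf"))
  m <- config$m_snps
  mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  bases <- c("A", "C", "G", "T")
  counted <- sample(bases, m, replace = TRUE)
  other <- vapply(counted, function(b) sample(setdiff(bases, b), 1L), "")
  list(snp_ids = paste0(config$snp_prefix, seq_len(m)),
       mafs = mafs,
       counted = counted, other = unname(other),
       pos = config$locus_start + (seq_len(m) - 1L) * config$snp_spacing)
}

# n_hap haplotypes x m SNPs: latent AR(1) Gaussian thresholded at the MAF
# quantile; allele 1 is the counted (minor) allele.
.sim_haplotypes <- function(n_hap, mafs, rho) {
  m <- length(mafs)
  thr <- stats::qnorm(mafs)
  H <- matrix(0L, n_hap, m)
  z <- stats::rnorm(n_hap)
  H[, 1] <- as.integer(z < thr[1])
  if (m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) {
      z <- rho * z + s * stats::rnorm(n_hap)
      H[, j] <- as.integer(z < thr[j])
    }
  }
  H
}

#' Simulate a genotype panel for one cohort
#'
#' Each individual's dosage is the sum of two haplotypes drawn from the
#' latent AR(1) model; the three cohorts (`"exposure"`, `"outcome"`,
#' `"reference"`) use independent named sub-streams of the master seed.
#'
#' @param config A [sim_config()].
#' @param cohort Which cohort to draw.
#' @param n Override the cohort size from the config.
#' @return A [genotype_panel()].
#' @export
simulate_genotypes <- function(config,
                               cohort = c("reference", "exposure", "outcome"),
                               n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- match.arg(cohort)
  layout <- .locus_layout(config)
  n <- n %||% switch(cohort, exposure = config$n_exposure,
                     outcome = config$n_outcome, reference = config$n_ref)
  set.seed(derive_seed(config$seed, cohort))
  H <- .sim_haplotypes(2L * n, layout$mafs, config$ld_rho)
  X <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  colnames(X) <- layout$snp_ids
  genotype_panel(X, data.frame(snp_id = layout$snp_ids,
                               counted_allele = layout$counted,
                               other_allele = layout$other,
                               stringsAsFactors = FALSE))
}

# Vectorized per-SNP simple least squares: marginal beta, se, p.
.marginal_ols <- function(X, y) {
  n <- nrow(X)
  xbar <- colMeans(X)
  Sxx <- colSums(X^2) - n * xbar^2
  Sxx[Sxx <= 0] <- NA_real_
  yc <- y - mean(y)
  Sxy <- as.vector(crossprod(X, yc))
  Syy <- sum(yc^2)
  b <- Sxy / Sxx
  rss <- pmax(Syy - b * Sxy, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  z <- b / se
  list(beta = b, se = se, pvalue = 2 * stats::pnorm(-abs(z)), n = n)
}

# Single-SNP logistic score test: beta = U/V, se = 1/sqrt(V) with
# U = x'(y - ybar), V = ybar(1 - ybar) Sxx.  Standard GWAS approximation
# on the log-odds scale.
.marginal_logistic_score <- function(X, y) {
  n <- nrow(X)
  ybar <- mean(y)
  xbar <- colMeans(X)
  Sxx <- colSums(X^2) - n * xbar^2
  Sxx[Sxx <= 0] <- NA_real_
  U <- as.vector(crossprod(X, y - ybar))
  V <- ybar * (1 - ybar) * Sxx
  list(beta = U / V, se = 1 / sqrt(V),
       pvalue = 2 * stats::pnorm(-abs(U / sqrt(V))), n = n)
}

.effect_vector <- function(causals, m) {
  b <- numeric(m)
  for (ce in causals) b[ce$index] <- b[ce$index] + ce$effect
  b
}

# Default direct outcome effects per architecture.
.derive_outcome_causals <- function(config) {
  if (!is.null(config$outcome_causals)) return(config$outcome_causals)
  switch(config$outcome_architecture,
    null = list(),
    shared = list(),   # effect flows through theta * exposure score
    distinct = {
      # place the outcome causal far enough from the exposure causal that
      # the latent correlation^2 stays below 0.3
      lag <- if (config$ld_rho > 0)
        max(2L, ceiling(log(0.3) / (2 * log(config$ld_rho)))) else 2L
      idx0 <- config$exposure_causals[[1]]$index
      idx <- if (idx0 + lag <= config$m_snps) idx0 + lag else idx0 - lag
      if (idx < 1) stop("cannot place a distinct outcome causal in this locus")
      list(list(index = as.integer(idx),
                effect = config$exposure_causals[[1]]$effect))
    },
    two_signal_one_shared =
      # the first exposure signal is the shared one
      list(list(index = config$exposure_causals[[1]]$index,
                effect = config$exposure_causals[[1]]$effect)))
}

.make_sumstat_table <- function(layout, stats, config, trait_id, trait_type,
                                eaf) {
  sumstat_table(data.frame(
    snp_id = layout$snp_ids, chrom = config$chrom, pos = layout$pos,
    effect_allele = layout$counted, other_allele = layout$other,
    eaf = eaf, beta = stats$beta, se = stats$se, pvalue = stats$pvalue,
    n = stats$n, stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type, quiet = TRUE)
}

#' Simulate exposure/outcome summary statistics, a reference panel and truth
#'
#' The exposure phenotype is a linear-additive function of standardized
#' causal dosages plus Gaussian noise scaled to approximately unit total
#' variance.  The outcome liability depends on the architecture: `shared`
#' routes `theta` times the genetic exposure score into the outcome;
#' `distinct` places its own causal variant(s) in the same LD block;
#' `two_signal_one_shared` gives the outcome a direct effect at the first
#' exposure signal only; `null` is pure noise.  Binary outcomes threshold
#' the liability at the configured case fraction and report logistic
#' score-test summary statistics (log-odds scale) by default.
#'
#' @param config A [sim_config()].
#' @return List with elements `exposure` and `outcome`
#'   ([sumstat_table()]s), `panel` (reference [genotype_panel()]),
#'   `annotation` (per-SNP [variant_annotation()] rows), and `truth`
#'   (`sim_truth`: causal indices/effects per trait, theta, shared flag,
#'   generating parameters, seed).
#' @export
simulate_locus_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- .locus_layout(config)
  m <- config$m_snps
  b_exp <- .effect_vector(config$exposure_causals, m)
  out_causals <- .derive_outcome_causals(config)
  b_out_direct <- .effect_vector(out_causals, m)

  # exposure cohort
  Xe <- simulate_genotypes(config, "exposure")$dosages
  set.seed(derive_seed(config$seed, "pheno_exposure"))
  Ze <- scale(Xe)
  g_e <- as.vector(Ze %*% b_exp)
  noise_var <- max(1e-6, 1 - stats::var(g_e))
  y_e <- g_e + stats::rnorm(nrow(Xe), 0, sqrt(noise_var))
  exp_stats <- .marginal_ols(Xe, y_e)
  exposure <- .make_sumstat_table(layout, exp_stats, config, "exposure",
                                  "quantitative", colMeans(Xe) / 2)

  # outcome cohort
  Xo <- simulate_genotypes(config, "outcome")$dosages
  set.seed(derive_seed(config$seed, "pheno_outcome"))
  Zo <- scale(Xo)
  g_shared <- if (config$outcome_architecture == "shared")
    config$theta * as.vector(Zo %*% b_exp) else 0
  g_direct <- if (any(b_out_direct != 0)) as.vector(Zo %*% b_out_direct) else 0
  g_o <- g_shared + g_direct
  noise_var_o <- max(1e-6, 1 - stats::var(if (length(g_o) > 1) g_o else numeric(nrow(Xo))))
  liab <- g_o + stats::rnorm(nrow(Xo), 0, sqrt(noise_var_o))
  if (config$outcome_type == "binary") {
    y_o <- as.integer(liab > stats::qnorm(1 - config$case_fraction,
                                          sd = stats::sd(liab)))
    out_stats <- if (config$binary_model == "linear")
      .marginal_ols(Xo, y_o) else .marginal_logistic_score(Xo, y_o)
  } else {
    y_o <- liab
    out_stats <- .marginal_ols(Xo, y_o)
  }
  outcome <- .make_sumstat_table(layout, out_stats, config, "outcome",
                                 config$outcome_type, colMeans(Xo) / 2)

  panel <- simulate_genotypes(config, "reference")

  annotation <- variant_annotation(data.frame(
    snp_id = layout$snp_ids, gene = "GENE1",
    tss_pos = config$locus_start, protein_altering = FALSE,
    stringsAsFactors = FALSE))

  truth <- structure(list(
    exposure_causals = config$exposure_causals,
    outcome_causals = out_causals,
    theta = if (config$outcome_architecture == "shared") config$theta else 0,
    shared = config$outcome_architecture %in% c("shared",
                                                "two_signal_one_shared"),
    architecture = config$outcome_architecture,
    mafs = layout$mafs, ld_rho = config$ld_rho,
    model = "linear_additive_exposure",
    seed = config$seed), class = "sim_truth")

  list(exposure = exposure, outcome = outcome, panel = panel,
       annotation = annotation, truth = truth)
}

#' Simulate a desk-scale proteome of independent loci
#'
#' A stand-in for a proteome-wide screen: `n_proteins` independent loci, a
#' configured subset carrying a true shared causal effect on the outcome
#' and the rest null.  Deterministic under the master seed.
#'
#' @param n_proteins Number of proteins.
#' @param causal Integer indices of the truly causal proteins (shared
#'   architecture); all others are null.
#' @param base_config Template [sim_config()]; per-protein configs differ
#'   only in seed, architecture, coordinates and SNP-id prefix.
#' @param seed Master seed (overrides `base_config$seed`).
#' @return List with `proteins` (named list of locus-pair lists, one per
#'   protein), and `truth` (data.frame: protein_id, gene, causal, theta).
#' @export
simulate_proteome <- function(n_proteins, causal = integer(0),
                              base_config = sim_config(), seed = 1L) {
  stopifnot(n_proteins >= 1, all(causal >= 1), all(causal <= n_proteins))
  proteins <- vector("list", n_proteins)
  ids <- sprintf("P%03d", seq_len(n_proteins))
  genes <- sprintf("GENE%03d", seq_len(n_proteins))
  for (i in seq_len(n_proteins)) {
    cfg <- base_config
    cfg$seed <- derive_seed(seed, "proteome", i)
    cfg$outcome_architecture <- if (i %in% causal) "shared" else "null"
    cfg$chrom <- as.character((i - 1L) %% 22L + 1L)
    cfg$locus_start <- as.integer(1e6 + ((i - 1L) %/% 22L) * 5e6)
    cfg$snp_prefix <- sprintf("%s_rs", ids[i])
    lp <- simulate_locus_pair(cfg)
    lp$annotation$gene <- genes[i]
    attr(lp$exposure, "trait_id") <- ids[i]
    proteins[[i]] <- lp
  }
  names(proteins) <- ids
  list(proteins = proteins,
       truth = data.frame(protein_id = ids, gene = genes,
                          causal = seq_len(n_proteins) %in% causal,
                          theta = ifelse(seq_len(n_proteins) %in% causal,
                                         base_config$theta, 0),
                          stringsAsFactors = FALSE))
}

#' Construct a variant annotation table
#'
#' @param df data.frame with columns `snp_id`, `gene`, `tss_pos`,
#'   `protein_altering`.
#' @return A `variant_annotation` data.frame.
#' @export
variant_annotation <- function(df) {
  stopifnot(all(c("snp_id", "gene", "tss_pos", "protein_altering") %in%
                  names(df)))
  df$snp_id <- as.character(df$snp_id)
  df$gene <- as.character(df$gene)
  df$tss_pos <- as.integer(df$tss_pos)
  df$protein_altering <- as.logical(df$protein_altering)
  structure(df[c("snp_id", "gene", "tss_pos", "protein_altering")],
            class = c("variant_annotation", "data.frame"))
}
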