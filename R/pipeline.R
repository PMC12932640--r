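# Proteome-wide driver: per-protein instrument selection -> MR ->
# Bonferroni screen -> PWCoCo follow-up for the significant proteins ->
# results table.  The Bonferroni denominator is the number of proteins
# with at least one valid instrument, not the number supplied.

#' Default pipeline parameters
#'
#' @return Named list of every tunable the pipeline consumes: instrument
#'   selection (`cis_window`, `p_threshold`, `maf_min`, `r2_threshold`),
#'   MR (`het_alpha`, `alpha`), colocalization (`priors`, `prior_sd1`,
#'   `prior_sd2`, `pp4_threshold`, `coloc_window`), conditional analysis
#'   (`p_cutoff`, `collinearity_r2`) and `single_signal_condition`.
#' @export
pipeline_params <- function() {
  list(cis_window = 1e6, p_threshold = 5e-8, maf_min = 0.01,
       r2_threshold = 0.01, het_alpha = 0.05, alpha = 0.05,
       priors = coloc_priors(), prior_sd1 = NULL, prior_sd2 = NULL,
       pp4_threshold = 0.8, coloc_window = 5e5,
       p_cutoff = 5e-8, collinearity_r2 = 0.9,
       single_signal_condition = FALSE)
}

.merge_params <- function(params) {
  base <- pipeline_params()
  for (nm in names(params)) base[[nm]] <- params[[nm]]
  if (!inherits(base$priors, "coloc_priors")) {
    base$priors <- do.call(coloc_priors, as.list(base$priors))
  }
  base
}

# Restrict a sumstat table to SNPs within `window` of `center_pos`.
.region_subset <- function(tab, center_pos, window) {
  df <- as.data.frame(tab)
  keep <- abs(df$pos - center_pos) <= window
  sumstat_table(df[keep, , drop = FALSE], trait_id = attr(tab, "trait_id"),
                trait_type = attr(tab, "trait_type"), quiet = TRUE)
}

#' Run the proteome-wide MR + PWCoCo screen
#'
#' For every protein: instruments are selected and harmonized, MR is run,
#' the Bonferroni threshold is derived from the count of proteins with at
#' least one valid instrument, and only Bonferroni-significant proteins
#' proceed to pairwise conditional colocalization (the screening gate).
#' Proteins with zero valid instruments are reported as `not_testable`.
#'
#' @param proteins Named list; each element a list with `exposure`
#'   ([sumstat_table()]), `annotation` ([variant_annotation()]), `panel`
#'   ([genotype_panel()]) and either its own `outcome` table or a shared
#'   one passed via `outcome`.
#' @param outcome Optional shared outcome [sumstat_table()].
#' @param params Overrides of [pipeline_params()].
#' @return A `proteome_report`: list(reports, table, bonferroni_threshold,
#'   n_tested, params).  `table` is a data.frame with one row per protein
#'   (gene, protein, beta, se, pvalue, method, n_snps, Q, q_pvalue,
#'   significant, colocalization, best_pp4).
#' @export
run_proteome_mr <- function(proteins, outcome = NULL, params = list()) {
  params <- .merge_params(params)
  ids <- names(proteins) %||% sprintf("P%03d", seq_along(proteins))

  prepared <- lapply(seq_along(proteins), function(i) {
    p <- proteins[[i]]
    out_tab <- p$outcome %||% outcome
    if (is.null(out_tab)) stop("no outcome table for protein ", ids[i])
    gene <- p$gene %||% p$annotation$gene[1]
    iset <- select_instruments(p$exposure, p$annotation, out_tab, p$panel,
                               gene = gene, protein_id = ids[i],
                               cis_window = params$cis_window,
                               p_threshold = params$p_threshold,
                               maf_min = params$maf_min,
                               r2_threshold = params$r2_threshold)
    list(id = ids[i], gene = gene, iset = iset, outcome = out_tab, data = p)
  })

  testable <- vapply(prepared, function(x) nrow(x$iset$instruments) > 0L,
                     TRUE)
  n_tested <- sum(testable)
  thr <- if (n_tested > 0) bonferroni_threshold(params$alpha, n_tested) else NA_real_

  reports <- lapply(prepared, function(x) {
    if (nrow(x$iset$instruments) == 0L) {
      return(structure(list(protein_id = x$id, gene = x$gene,
                            instruments = x$iset, mr = NULL, pwcoco = NULL,
                            verdict = "not_testable"),
                       class = "protein_report"))
    }
    mr <- ivw(x$iset, het_alpha = params$het_alpha)
    significant <- mr$pvalue < thr
    pw <- NULL
    verdict <- "not_tested"
    if (isTRUE(significant)) {
      lead <- x$iset$instruments$snp_id[which.min(x$iset$instruments$p_exp)]
      lead_pos <- as.data.frame(x$data$exposure)$pos[
        match(lead, x$data$exposure$snp_id)]
      exp_reg <- .region_subset(x$data$exposure, lead_pos,
                                params$coloc_window)
      out_reg <- .region_subset(x$outcome, lead_pos, params$coloc_window)
      ws1 <- cojo_workspace(exp_reg, x$data$panel,
                            collinearity_r2 = params$collinearity_r2)
      ws2 <- cojo_workspace(out_reg, x$data$panel,
                            collinearity_r2 = params$collinearity_r2)
      pw <- run_pwcoco(ws1, ws2, priors = params$priors,
                       prior_sd1 = params$prior_sd1,
                       prior_sd2 = params$prior_sd2,
                       pp4_threshold = params$pp4_threshold,
                       p_cutoff = params$p_cutoff,
                       single_signal_condition = params$single_signal_condition)
      verdict <- if (pw$evidence) "yes" else "no"
    }
    structure(list(protein_id = x$id, gene = x$gene, instruments = x$iset,
                   mr = mr, significant = isTRUE(significant),
                   pwcoco = pw, verdict = verdict),
              class = "protein_report")
  })
  names(reports) <- ids

  table <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$mr)) {
      data.frame(gene = r$gene, protein = r$protein_id, beta = NA_real_,
                 se = NA_real_, pvalue = NA_real_, method = NA_character_,
                 n_snps = 0L, Q = NA_real_, q_pvalue = NA_real_,
                 significant = FALSE, colocalization = "not_testable",
                 best_pp4 = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = r$gene, protein = r$protein_id, beta = r$mr$theta,
                 se = r$mr$se_theta, pvalue = r$mr$pvalue,
                 method = r$mr$method, n_snps = r$mr$n_snps, Q = r$mr$Q,
                 q_pvalue = r$mr$q_pvalue, significant = r$significant,
                 colocalization = r$verdict,
                 best_pp4 = if (is.null(r$pwcoco)) NA_real_ else
                   r$pwcoco$best_pp4,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(table) <- NULL
  structure(list(reports = reports, table = table,
                 bonferroni_threshold = thr, n_tested = n_tested,
                 params = params),
            class = "proteome_report")
}

#' @export
print.proteome_report <- function(x, ...) {
  cat(sprintf("proteome_report: %d protein(s), %d testable, Bonferroni p < %.3g\n",
              nrow(x$table), x$n_tested, x$bonferroni_threshold))
  cat(sprintf("  significant: %d; colocalized: %d\n",
              sum(x$table$significant),
              sum(x$table$colocalization == "yes")))
  invisible(x)
}

#' Re-run the MR stage against alternative outcome traits
#'
#' Applies the identical instrument-selection and MR machinery per
#' (protein, outcome) pair — e.g. heel BMD, total-body BMD, any-fracture
#' analogues.  Both nominal and Bonferroni-adjusted significance flags
#' are reported per outcome.
#'
#' @param proteins As in [run_proteome_mr()].
#' @param outcomes Named list of outcome [sumstat_table()]s.
#' @param params Overrides of [pipeline_params()].
#' @return data.frame with one row per (protein, outcome): gene, protein,
#'   outcome, beta, se, pvalue, method, n_snps, nominal_significant,
#'   significant_bonferroni, verdict.
#' @export
run_secondary_outcomes <- function(proteins, outcomes, params = list()) {
  params <- .merge_params(params)
  ids <- names(proteins) %||% sprintf("P%03d", seq_along(proteins))
  rows <- list()
  for (oname in names(outcomes)) {
    out_tab <- outcomes[[oname]]
    prepared <- lapply(seq_along(proteins), function(i) {
      p <- proteins[[i]]
      gene <- p$gene %||% p$annotation$gene[1]
      iset <- try(select_instruments(p$exposure, p$annotation, out_tab,
                                     p$panel, gene = gene,
                                     protein_id = ids[i],
                                     cis_window = params$cis_window,
                                     p_threshold = params$p_threshold,
                                     maf_min = params$maf_min,
                                     r2_threshold = params$r2_threshold),
                  silent = TRUE)
      list(id = ids[i], gene = gene, iset = iset)
    })
    ok <- vapply(prepared, function(x)
      !inherits(x$iset, "try-error") && nrow(x$iset$instruments) > 0L, TRUE)
    thr <- if (any(ok)) bonferroni_threshold(params$alpha, sum(ok)) else NA_real_
    for (x in prepared) {
      if (inherits(x$iset, "try-error") || nrow(x$iset$instruments) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = x$gene, protein = x$id, outcome = oname, beta = NA_real_,
          se = NA_real_, pvalue = NA_real_, method = NA_character_,
          n_snps = 0L, nominal_significant = FALSE,
          significant_bonferroni = FALSE, verdict = "not_testable",
          stringsAsFactors = FALSE)
      } else {
        mr <- ivw(x$iset, het_alpha = params$het_alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = x$gene, protein = x$id, outcome = oname, beta = mr$theta,
          se = mr$se_theta, pvalue = mr$pvalue, method = mr$method,
          n_snps = mr$n_snps,
          nominal_significant = mr$pvalue < params$alpha,
          significant_bonferroni = mr$pvalue < thr, verdict = "tested",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render the per-protein results as a formatted table
#'
#' Proteins are sorted by ascending MR p-value; beta and SE are shown to
#' two decimals and p in scientific notation with two significant digits
#' (e.g. `6.5E-43`).
#'
#' @param report A `proteome_report` (or its `table` data.frame).
#' @param significant_only Keep only Bonferroni-significant proteins.
#' @return data.frame of formatted character columns: Gene, Protein,
#'   Beta, SE, P, Colocalization.
#' @export
render_results_table <- function(report, significant_only = FALSE) {
  tab <- if (inherits(report, "proteome_report")) report$table else report
  tab <- tab[!is.na(tab$pvalue), , drop = FALSE]
  if (significant_only) tab <- tab[tab$significant, , drop = FALSE]
  tab <- tab[order(tab$pvalue), , drop = FALSE]
  out <- data.frame(Gene = tab$gene, Protein = tab$protein,
                    Beta = sprintf("%.2f", tab$beta),
                    SE = sprintf("%.2f", tab$se),
                    P = toupper(sprintf("%.1e", tab$pvalue)),
                    Colocalization = ifelse(tab$colocalization == "yes",
                                            "Yes",
                                            ifelse(tab$colocalization == "no",
                                                   "No", "-")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a variant annotation table from a tab-delimited file
#'
#' @param path File with header columns snp_id, gene, tss_pos,
#'   protein_altering.
#' @return A [variant_annotation()].
#' @export
read_annotation <- function(path) {
  variant_annotation(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
}

#' Write a variant annotation table
#' @param annotation A [variant_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation ground-truth record as key-value text
#'
#' @param truth A `sim_truth` from [simulate_locus_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  fmt_causals <- function(cs) {
    paste(vapply(cs, function(ce) sprintf("%d:%g", ce$index, ce$effect), ""),
          collapse = ",")
  }
  lines <- c(
    paste0("architecture\t", truth$architecture),
    paste0("exposure_causals\t", fmt_causals(truth$exposure_causals)),
    paste0("outcome_causals\t", fmt_causals(truth$outcome_causals)),
    paste0("theta\t", format(truth$theta, digits = 17)),
    paste0("shared\t", truth$shared),
    paste0("ld_rho\t", format(truth$ld_rho, digits = 17)),
    paste0("model\t", truth$model),
    paste0("seed\t", truth$seed))
  writeLines(lines, path)
  invisible(path)
}
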