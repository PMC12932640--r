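# Cis-pQTL instrument selection, harmonization and LD pruning.
#
# Selection rules: SNPs within the cis window of the protein's gene,
# below the instrument p-value threshold, not protein-altering, with
# MAF > 1%, present in the outcome GWAS; palindromic SNPs with allele
# frequency in [0.45, 0.55] are removed; surviving SNPs are harmonized to
# a shared effect allele and greedily LD-pruned (r^2 <= 0.01, keeping the
# most significant pQTL).  Every exclusion is logged with a reason code so
# retained + excluded partition the input.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) unname(.COMPLEMENT[ea] == oa)

#' Select candidate cis-pQTL instruments for one protein
#'
#' @param exposure [sumstat_table()] of protein (exposure) associations.
#' @param annotation [variant_annotation()] covering the candidate SNPs.
#' @param outcome [sumstat_table()] for the outcome trait.
#' @param gene Gene symbol of the protein; its TSS is looked up in
#'   `annotation`.
#' @param cis_window Half-width of the closed cis window around the TSS
#'   (default 1 Mb).
#' @param p_threshold Instrument significance threshold on the exposure
#'   association (default genome-wide, 5e-8).
#' @param maf_min Strict lower bound on minor allele frequency (default
#'   0.01, i.e. MAF above 1%).
#' @return List with `candidates` (retained exposure rows) and
#'   `exclusions` (data.frame snp_id, reason).
#' @export
select_cis_pqtls <- function(exposure, annotation, outcome, gene,
                             cis_window = 1e6, p_threshold = 5e-8,
                             maf_min = 0.01) {
  stopifnot(inherits(exposure, "sumstat_table"),
            inherits(outcome, "sumstat_table"))
  tss <- unique(annotation$tss_pos[annotation$gene == gene])
  if (length(tss) == 0L) stop("gene not present in annotation: ", gene)
  tss <- tss[1]

  df <- as.data.frame(exposure)
  idx <- match(df$snp_id, annotation$snp_id)
  reason <- rep(NA_character_, nrow(df))
  mark <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  mark(is.na(idx), "no_annotation")
  mark(abs(df$pos - tss) > cis_window, "cis_window")
  mark(df$pvalue >= p_threshold, "pvalue")
  mark(annotation$protein_altering[idx], "protein_altering")
  mark(pmin(df$eaf, 1 - df$eaf) <= maf_min, "maf")
  mark(!(df$snp_id %in% outcome$snp_id), "not_in_outcome")

  keep <- is.na(reason)
  list(candidates = df[keep, , drop = FALSE],
       exclusions = data.frame(snp_id = df$snp_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Remove frequency-ambiguous palindromic SNPs
#'
#' Palindromic SNPs (A/T or C/G allele pairs) with effect-allele frequency
#' inside the inclusive band `[0.45, 0.55]` cannot be oriented and are
#' removed; palindromic SNPs outside the band are retained and flagged for
#' frequency-based orientation during harmonization.
#'
#' @param candidates data.frame of exposure rows (from
#'   [select_cis_pqtls()]).
#' @param band Inclusive ambiguity band on the effect-allele frequency.
#' @return List with `candidates` (with a logical `palindromic` column)
#'   and `exclusions`.
#' @export
remove_palindromic <- function(candidates, band = c(0.45, 0.55)) {
  if (nrow(candidates) == 0L) {
    candidates$palindromic <- logical(0)
    return(list(candidates = candidates,
                exclusions = data.frame(snp_id = character(0),
                                        reason = character(0))))
  }
  pal <- .is_palindromic(candidates$effect_allele, candidates$other_allele)
  drop <- pal & candidates$eaf >= band[1] & candidates$eaf <= band[2]
  out <- candidates[!drop, , drop = FALSE]
  out$palindromic <- pal[!drop]
  list(candidates = out,
       exclusions = data.frame(snp_id = candidates$snp_id[drop],
                               reason = rep("palindromic_ambiguous_freq",
                                            sum(drop)),
                               stringsAsFactors = FALSE))
}

#' Harmonize exposure and outcome records to a shared effect allele
#'
#' Outcome records listing the same allele pair in swapped orientation get
#' their beta negated and frequency reflected; strand-flipped
#' non-palindromic pairs are aligned by complementing; retained
#' palindromic SNPs are oriented by matching allele-frequency sides (both
#' below or both above 0.5) and removed when the outcome frequency is
#' itself ambiguous (inside `[0.45, 0.55]`); anything else is removed with
#' reason `allele_mismatch`.
#'
#' @param candidates data.frame from [remove_palindromic()] (must carry a
#'   `palindromic` column; it is recomputed if absent).
#' @param outcome [sumstat_table()] for the outcome.
#' @return List with `instruments` (harmonized data.frame: snp_id,
#'   effect_allele, other_allele, beta_exp, se_exp, p_exp, eaf_exp,
#'   beta_out, se_out, p_out, eaf_out, n_exp, n_out) and `exclusions`.
#' @export
harmonize <- function(candidates, outcome, band = c(0.45, 0.55)) {
  if (is.null(candidates$palindromic)) {
    candidates$palindromic <- .is_palindromic(candidates$effect_allele,
                                              candidates$other_allele)
  }
  o <- as.data.frame(outcome)
  j <- match(candidates$snp_id, o$snp_id)
  n_c <- nrow(candidates)
  beta_out <- se_out <- p_out <- eaf_out <- n_out <- rep(NA_real_, n_c)
  reason <- rep(NA_character_, n_c)

  for (i in seq_len(n_c)) {
    if (is.na(j[i])) { reason[i] <- "not_in_outcome"; next }
    ea <- candidates$effect_allele[i]; oa <- candidates$other_allele[i]
    orow <- o[j[i], ]
    ea2 <- orow$effect_allele; oa2 <- orow$other_allele
    flip <- NA  # FALSE = aligned, TRUE = negate outcome beta
    if (candidates$palindromic[i]) {
      if (!setequal(c(ea2, oa2), c(ea, oa))) { reason[i] <- "allele_mismatch"; next }
      if (orow$eaf >= band[1] && orow$eaf <= band[2]) {
        reason[i] <- "palindromic_ambiguous_freq"; next
      }
      # orient by frequency side; treat the outcome's listed effect allele
      # as matching when both frequencies fall on the same side of 0.5
      same_label <- (ea2 == ea)
      eaf_as_labelled <- if (same_label) orow$eaf else 1 - orow$eaf
      flip <- (candidates$eaf[i] < 0.5) != (eaf_as_labelled < 0.5)
      if (!same_label) { # relabel to exposure orientation first
        beta_out[i] <- -orow$beta; eaf_out[i] <- 1 - orow$eaf
      } else {
        beta_out[i] <- orow$beta; eaf_out[i] <- orow$eaf
      }
      if (flip) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
    } else {
      cea2 <- .COMPLEMENT[[ea2]]; coa2 <- .COMPLEMENT[[oa2]]
      if (ea2 == ea && oa2 == oa) {
        beta_out[i] <- orow$beta; eaf_out[i] <- orow$eaf
      } else if (ea2 == oa && oa2 == ea) {
        beta_out[i] <- -orow$beta; eaf_out[i] <- 1 - orow$eaf
      } else if (cea2 == ea && coa2 == oa) {
        beta_out[i] <- orow$beta; eaf_out[i] <- orow$eaf
      } else if (cea2 == oa && coa2 == ea) {
        beta_out[i] <- -orow$beta; eaf_out[i] <- 1 - orow$eaf
      } else {
        reason[i] <- "allele_mismatch"; next
      }
    }
    se_out[i] <- orow$se; p_out[i] <- orow$pvalue; n_out[i] <- orow$n
  }

  keep <- is.na(reason)
  instruments <- data.frame(
    snp_id = candidates$snp_id[keep],
    effect_allele = candidates$effect_allele[keep],
    other_allele = candidates$other_allele[keep],
    beta_exp = candidates$beta[keep], se_exp = candidates$se[keep],
    p_exp = candidates$pvalue[keep], eaf_exp = candidates$eaf[keep],
    beta_out = beta_out[keep], se_out = se_out[keep], p_out = p_out[keep],
    eaf_out = eaf_out[keep],
    n_exp = candidates$n[keep], n_out = n_out[keep],
    palindromic = candidates$palindromic[keep],
    stringsAsFactors = FALSE)
  list(instruments = instruments,
       exclusions = data.frame(snp_id = candidates$snp_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Greedy LD pruning keeping the most significant pQTLs
#'
#' Instruments are sorted by exposure p-value (ties by |z| descending,
#' then snp_id) and accepted greedily: a SNP is kept iff its reference
#' r^2 with every already-accepted SNP is at or below the threshold.
#'
#' @param instruments Harmonized instrument data.frame (from
#'   [harmonize()]).
#' @param panel Reference [genotype_panel()] containing all instruments.
#' @param r2_threshold Pairwise r^2 ceiling (default 0.01).
#' @param protein_id Label stored on the returned set.
#' @param exclusions Upstream exclusion log to carry through.
#' @return An `instrument_set`: list(protein_id, instruments, exclusions).
#' @export
ld_prune <- function(instruments, panel, r2_threshold = 0.01,
                     protein_id = "protein",
                     exclusions = data.frame(snp_id = character(0),
                                             reason = character(0))) {
  missing <- setdiff(instruments$snp_id, panel$snp_ids)
  if (length(missing) > 0L) {
    stop("instrument(s) absent from reference panel: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(instruments) > 0L) {
    z <- abs(instruments$beta_exp / instruments$se_exp)
    ord <- order(instruments$p_exp, -z, instruments$snp_id)
    inst <- instruments[ord, , drop = FALSE]
    R <- if (nrow(inst) > 1L) ld_matrix(panel, inst$snp_id) else
      matrix(1, 1, 1, dimnames = list(inst$snp_id, inst$snp_id))
    accepted <- integer(0)
    pruned <- character(0)
    for (i in seq_len(nrow(inst))) {
      if (length(accepted) == 0L ||
          all(R[i, accepted]^2 <= r2_threshold)) {
        accepted <- c(accepted, i)
      } else {
        pruned <- c(pruned, inst$snp_id[i])
      }
    }
    inst_keep <- inst[accepted, , drop = FALSE]
    rownames(inst_keep) <- NULL
    if (length(pruned) > 0L) {
      exclusions <- rbind(exclusions,
                          data.frame(snp_id = pruned,
                                     reason = rep("ld_prune", length(pruned)),
                                     stringsAsFactors = FALSE))
    }
  } else {
    inst_keep <- instruments
  }
  structure(list(protein_id = protein_id, instruments = inst_keep,
                 exclusions = exclusions, r2_threshold = r2_threshold),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set '%s': %d instrument(s), %d exclusion(s)\n",
              x$protein_id, nrow(x$instruments), nrow(x$exclusions)))
  invisible(x)
}

#' Full instrument-selection chain for one protein
#'
#' Runs [select_cis_pqtls()], [remove_palindromic()], [harmonize()] and
#' [ld_prune()] in sequence, accumulating the exclusion log, so that every
#' exposure SNP appears exactly once across retained instruments and
#' logged exclusions.
#'
#' @inheritParams select_cis_pqtls
#' @inheritParams ld_prune
#' @param protein_id Label for the returned set.
#' @return An `instrument_set`.
#' @export
select_instruments <- function(exposure, annotation, outcome, panel, gene,
                               protein_id = gene,
                               cis_window = 1e6, p_threshold = 5e-8,
                               maf_min = 0.01, r2_threshold = 0.01) {
  s1 <- select_cis_pqtls(exposure, annotation, outcome, gene,
                         cis_window = cis_window, p_threshold = p_threshold,
                         maf_min = maf_min)
  s2 <- remove_palindromic(s1$candidates)
  s3 <- harmonize(s2$candidates, outcome)
  log <- rbind(s1$exclusions, s2$exclusions, s3$exclusions)
  ld_prune(s3$instruments, panel, r2_threshold = r2_threshold,
           protein_id = protein_id, exclusions = log)
}
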