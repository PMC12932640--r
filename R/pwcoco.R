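# Pairwise conditional colocalization.
#
# Unconditional colocalization first; if PP.H4 is already at or above the
# evidence threshold, stop.  Otherwise select conditionally independent
# signals for each trait, build one signal-isolating conditional dataset
# per signal (conditioning on all the others), and colocalize every
# combination of {unconditional + conditionals} x {unconditional +
# conditionals}, reporting the maximum PP.H4 over all evaluations.

#' Build signal-isolating conditional datasets for one trait
#'
#' With k selected signals: k >= 2 yields k datasets, dataset s
#' conditioning on the other k - 1 signals so that signal s is isolated;
#' k = 1 yields none by default (the unconditional data already isolate
#' the signal) unless `single_signal_condition = TRUE`, in which case the
#' dataset conditioned on that single SNP is also produced; k = 0 yields
#' none.
#'
#' @param ws A [cojo_workspace()].
#' @param selected Selected independent SNPs (from [stepwise_select()]).
#' @param single_signal_condition Also condition on a lone signal.
#' @return Named list of `conditional_dataset`s (names = isolated signal,
#'   or `"cond_<snp>"` for the single-signal variant).
#' @export
make_conditional_datasets <- function(ws, selected,
                                      single_signal_condition = FALSE) {
  k <- length(selected)
  if (k == 0L) return(list())
  if (k == 1L) {
    if (!single_signal_condition) return(list())
    out <- list(conditional_stats(ws, selected))
    names(out) <- paste0("cond_", selected)
    return(out)
  }
  out <- lapply(seq_len(k), function(s) {
    conditional_stats(ws, setdiff(selected, selected[s]))
  })
  names(out) <- selected
  out
}

#' Run pairwise conditional colocalization for a region
#'
#' @param ws1,ws2 [cojo_workspace()]s for trait 1 (e.g. protein) and
#'   trait 2 (e.g. outcome), built over the same region; colocalization
#'   uses the intersection of their SNPs.
#' @param priors A [coloc_priors()].
#' @param prior_sd1,prior_sd2 Per-trait ABF prior effect SDs (defaults by
#'   trait type; see [abf()]).
#' @param pp4_threshold Evidence threshold on PP.H4 (default 0.8; the
#'   early exit uses `pp4 >= pp4_threshold`).
#' @param p_cutoff Stepwise-selection significance cutoff.
#' @param single_signal_condition Passed to
#'   [make_conditional_datasets()].
#' @return A `pwcoco_result`: `unconditional` posterior, `combinations`
#'   (named list of all evaluated posteriors incl. the unconditional
#'   pair), `best_pp4`, `best_combination`, `evidence`,
#'   `selected1`/`selected2`, `conditional_search_run`.
#' @export
run_pwcoco <- function(ws1, ws2, priors = coloc_priors(),
                       prior_sd1 = NULL, prior_sd2 = NULL,
                       pp4_threshold = 0.8, p_cutoff = 5e-8,
                       single_signal_condition = FALSE) {
  shared <- intersect(ws1$snp_id, ws2$snp_id)
  if (length(shared) == 0L) stop("no shared SNPs between the two traits")

  ds1_uncond <- data.frame(snp_id = ws1$snp_id, beta = ws1$b, se = ws1$se,
                           stringsAsFactors = FALSE)
  ds2_uncond <- data.frame(snp_id = ws2$snp_id, beta = ws2$b, se = ws2$se,
                           stringsAsFactors = FALSE)
  cc <- function(d1, d2, label) {
    coloc_datasets(d1, d2, ws1$trait_type, ws2$trait_type, priors,
                   prior_sd1, prior_sd2, label = label)
  }
  uncond <- cc(ds1_uncond, ds2_uncond, "unconditional/unconditional")
  combos <- list("unconditional/unconditional" = uncond)
  selected1 <- character(0); selected2 <- character(0)
  search_run <- FALSE

  if (uncond$pp4 < pp4_threshold) {
    search_run <- TRUE
    selected1 <- stepwise_select(ws1, p_cutoff = p_cutoff)
    selected2 <- stepwise_select(ws2, p_cutoff = p_cutoff)
    cds1 <- make_conditional_datasets(ws1, selected1,
                                      single_signal_condition)
    cds2 <- make_conditional_datasets(ws2, selected2,
                                      single_signal_condition)
    side1 <- c(list(unconditional = ds1_uncond),
               lapply(cds1, function(cd) cd$records))
    side2 <- c(list(unconditional = ds2_uncond),
               lapply(cds2, function(cd) cd$records))
    for (a in names(side1)) {
      for (b in names(side2)) {
        if (a == "unconditional" && b == "unconditional") next
        lab <- paste(a, b, sep = "/")
        combos[[lab]] <- cc(side1[[a]], side2[[b]], lab)
      }
    }
  }

  pp4s <- vapply(combos, function(x) x$pp4, 0)
  best <- which.max(pp4s)
  structure(list(unconditional = uncond, combinations = combos,
                 best_pp4 = unname(pp4s[best]),
                 best_combination = names(combos)[best],
                 evidence = unname(pp4s[best]) >= pp4_threshold,
                 pp4_threshold = pp4_threshold,
                 selected1 = selected1, selected2 = selected2,
                 conditional_search_run = search_run,
                 priors = priors),
            class = "pwcoco_result")
}

#' @export
print.pwcoco_result <- function(x, ...) {
  cat(sprintf("pwcoco_result: %d combination(s) evaluated\n",
              length(x$combinations)))
  cat(sprintf("  unconditional PP.H4 = %.4f\n", x$unconditional$pp4))
  cat(sprintf("  best PP.H4 = %.4f [%s]; evidence (>= %.2f): %s\n",
              x$best_pp4, x$best_combination, x$pp4_threshold,
              if (x$evidence) "yes" else "no"))
  if (x$conditional_search_run) {
    cat(sprintf("  selected signals: trait1 {%s} trait2 {%s}\n",
                paste(x$selected1, collapse = ", "),
                paste(x$selected2, collapse = ", ")))
  }
  invisible(x)
}

#' Tabulate every evaluated combination of a PWCoCo run
#'
#' @param result A `pwcoco_result`.
#' @return data.frame: combination, n_snps, pp0..pp4.
#' @export
pwcoco_table <- function(result) {
  do.call(rbind, lapply(names(result$combinations), function(lab) {
    p <- result$combinations[[lab]]
    data.frame(combination = lab, n_snps = p$n_snps, pp0 = p$pp0,
               pp1 = p$pp1, pp2 = p$pp2, pp3 = p$pp3, pp4 = p$pp4,
               stringsAsFactors = FALSE)
  }))
}
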