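# Wald-ratio / IVW Mendelian randomization with Cochran's Q driven
# fixed/random-effects choice, and the Bonferroni screen.

#' Wald ratio causal estimate from a single instrument
#'
#' `theta = beta_out / beta_exp`; the first-order delta-method standard
#' error `se = se_out / |beta_exp|` ignores the exposure uncertainty
#' (the conventional default); `second_order = TRUE` adds the exposure
#' term `theta^2 se_exp^2 / beta_exp^2`.
#'
#' @param beta_exp,se_exp Exposure effect and SE (SE used only for the
#'   second-order variant).
#' @param beta_out,se_out Outcome effect and SE.
#' @param second_order Include the exposure-uncertainty term.
#' @return List with `theta` and `se`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out, se_exp = NA_real_,
                       second_order = FALSE) {
  if (beta_exp == 0) stop("undefined Wald ratio: beta_exp = 0")
  theta <- beta_out / beta_exp
  v <- se_out^2 / beta_exp^2
  if (second_order) {
    if (!is.finite(se_exp)) stop("second_order = TRUE requires se_exp")
    v <- v + theta^2 * se_exp^2 / beta_exp^2
  }
  list(theta = theta, se = sqrt(v))
}

#' Two-sided z-test p-value
#'
#' Computed on the log-stable upper tail so extreme z-scores give exact
#' tiny (nonzero) p-values instead of underflowing through `1 - Phi(z)`.
#'
#' @param theta Estimate.
#' @param se Standard error (> 0).
#' @return `2 * (1 - Phi(|theta/se|))`.
#' @export
ztest_p <- function(theta, se) {
  stopifnot(all(se > 0))
  2 * stats::pnorm(abs(theta / se), lower.tail = FALSE)
}

#' Inverse-variance-weighted MR estimate for one protein
#'
#' Per-instrument Wald ratios are combined with weights `1/se(theta_j)^2`.
#' With a single instrument the result is the Wald ratio itself
#' (method `"wald"`).  Heterogeneity is measured by Cochran's Q with
#' `n_snps - 1` degrees of freedom; when its p-value falls below
#' `het_alpha` the random-effects variant is reported: same point
#' estimate, SE inflated multiplicatively by `sqrt(max(1, Q/df))`.
#'
#' @param instruments Harmonized instrument data.frame (columns
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`), or an `instrument_set`.
#' @param protein_id Label for the result (taken from an `instrument_set`
#'   automatically).
#' @param het_alpha Heterogeneity alpha for the fixed/random choice
#'   (default 0.05).
#' @param second_order Use second-order Wald-ratio SEs.
#' @return An `mr_result`: protein_id, theta, se_theta, pvalue, method
#'   (`wald`/`ivw_fixed`/`ivw_random`), n_snps, Q, q_df, q_pvalue.
#' @export
ivw <- function(instruments, protein_id = NULL, het_alpha = 0.05,
                second_order = FALSE) {
  if (inherits(instruments, "instrument_set")) {
    protein_id <- protein_id %||% instruments$protein_id
    instruments <- instruments$instruments
  }
  protein_id <- protein_id %||% "protein"
  k <- nrow(instruments)
  if (is.null(k) || k == 0L) stop("empty instrument set for ", protein_id)
  if (any(instruments$beta_exp == 0)) stop("beta_exp = 0 among instruments")

  wr <- mapply(function(be, bo, so, se) {
    unlist(wald_ratio(be, bo, so, se, second_order = second_order))
  }, instruments$beta_exp, instruments$beta_out, instruments$se_out,
     instruments$se_exp)
  theta_j <- wr["theta", ]
  se_j <- wr["se", ]
  w <- 1 / se_j^2
  theta_hat <- sum(w * theta_j) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))

  if (k == 1L) {
    method <- "wald"
    se_hat <- se_j[1]
    Q <- 0; q_df <- 0L; q_p <- NA_real_
  } else {
    Q <- sum(w * (theta_j - theta_hat)^2)
    q_df <- k - 1L
    q_p <- stats::pchisq(Q, df = q_df, lower.tail = FALSE)
    if (q_p < het_alpha) {
      method <- "ivw_random"
      se_hat <- se_fixed * sqrt(max(1, Q / q_df))
    } else {
      method <- "ivw_fixed"
      se_hat <- se_fixed
    }
  }
  structure(list(protein_id = protein_id,
                 theta = unname(theta_hat), se_theta = unname(se_hat),
                 pvalue = unname(ztest_p(theta_hat, se_hat)),
                 method = method, n_snps = k,
                 Q = unname(Q), q_df = q_df, q_pvalue = unname(q_p),
                 het_alpha = het_alpha,
                 snp_ids = instruments$snp_id),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("mr_result '%s': theta = %.4f (SE %.4f), p = %.3g, %s, %d SNP(s)\n",
              x$protein_id, x$theta, x$se_theta, x$pvalue, x$method, x$n_snps))
  if (x$n_snps > 1) {
    cat(sprintf("  Cochran's Q = %.3f on %d df (p = %.3g)\n",
                x$Q, x$q_df, x$q_pvalue))
  }
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (e.g. proteins with valid instruments).
#' @return `alpha / n_tests`; a result is Bonferroni-significant iff its
#'   p-value is strictly below this threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}
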