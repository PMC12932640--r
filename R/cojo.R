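# Approximate conditional and joint association analysis from summary
# statistics plus a reference LD panel (GCTA-COJO style).
#
# Per SNP j with marginal beta b_j, SE se_j, effect-allele frequency f_j
# and sample size n_j, the centered genotype sum of squares is
# approximated by D_j = 2 f_j (1 - f_j) n_j and the regional phenotypic
# sum of squares by the median over SNPs of D_j (b_j^2 + (n_j - 2) se_j^2).
# Joint fits then use (X'X)_{ij} ~ r_ij sqrt(D_i D_j), (X'y)_j = D_j b_j.

#' Build a COJO workspace from summary statistics and a reference panel
#'
#' Panel dosages are aligned to each record's effect allele (columns whose
#' counted allele is the record's other allele are reflected, `2 - x`);
#' SNPs absent from the panel or with incompatible alleles are dropped
#' with a logged reason.
#'
#' @param sumstats A [sumstat_table()].
#' @param panel A [genotype_panel()].
#' @param collinearity_r2 Pairwise r^2 above which SNPs are treated as
#'   collinear (default 0.9).
#' @param freq_warn Warn when |panel frequency - GWAS frequency| exceeds
#'   this (default 0.2, warn-only).
#' @return A `cojo_workspace`.
#' @export
cojo_workspace <- function(sumstats, panel, collinearity_r2 = 0.9,
                           freq_warn = 0.2) {
  stopifnot(inherits(sumstats, "sumstat_table"),
            inherits(panel, "genotype_panel"))
  df <- as.data.frame(sumstats)
  j <- match(df$snp_id, panel$snp_ids)
  dropped <- data.frame(snp_id = character(0), reason = character(0))
  keep <- !is.na(j)
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(snp_id = df$snp_id[!keep],
                                         reason = "not_in_panel"))
  }
  df <- df[keep, , drop = FALSE]; j <- j[keep]
  al <- panel$alleles[j, ]
  direct <- al$counted_allele == df$effect_allele &
    al$other_allele == df$other_allele
  flipped <- al$counted_allele == df$other_allele &
    al$other_allele == df$effect_allele
  ok <- direct | flipped
  if (any(!ok)) {
    dropped <- rbind(dropped, data.frame(snp_id = df$snp_id[!ok],
                                         reason = "allele_mismatch"))
    df <- df[ok, , drop = FALSE]; j <- j[ok]
    flipped <- flipped[ok]
  }
  if (nrow(df) == 0L) stop("no usable SNPs shared between sumstats and panel")
  X <- panel$dosages[, j, drop = FALSE]
  if (any(flipped)) X[, flipped] <- 2 - X[, flipped, drop = FALSE]
  colnames(X) <- df$snp_id
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    dropped <- rbind(dropped, data.frame(snp_id = df$snp_id[v == 0],
                                         reason = "constant_in_panel"))
    X <- X[, v > 0, drop = FALSE]
    df <- df[v > 0, , drop = FALSE]
  }
  panel_freq <- colMeans(X) / 2
  dev <- abs(panel_freq - df$eaf)
  if (any(dev > freq_warn)) {
    warning(sprintf("%d SNP(s) with |panel freq - GWAS freq| > %.2f: %s",
                    sum(dev > freq_warn), freq_warn,
                    paste(utils::head(df$snp_id[dev > freq_warn], 5),
                          collapse = ", ")))
  }
  D <- 2 * df$eaf * (1 - df$eaf) * df$n
  syy_j <- D * (df$beta^2 + (df$n - 2) * df$se^2)
  structure(list(snp_id = df$snp_id, b = df$beta, se = df$se,
                 f = df$eaf, n = df$n, pvalue = df$pvalue,
                 D = D, Syy = stats::median(syy_j),
                 n_eff = stats::median(df$n),
                 R = stats::cor(X),
                 trait_type = attr(sumstats, "trait_type"),
                 trait_id = attr(sumstats, "trait_id"),
                 collinearity_r2 = collinearity_r2,
                 dropped = dropped),
            class = "cojo_workspace")
}

#' @export
print.cojo_workspace <- function(x, ...) {
  cat(sprintf("cojo_workspace '%s': %d SNP(s), n_eff = %g, Syy = %.3g\n",
              x$trait_id, length(x$snp_id), x$n_eff, x$Syy))
  invisible(x)
}

.ws_index <- function(ws, snps) {
  i <- match(snps, ws$snp_id)
  if (anyNA(i)) stop("SNP(s) not in workspace: ",
                     paste(snps[is.na(i)], collapse = ", "))
  i
}

#' Joint (multi-SNP) effect estimates from summary statistics
#'
#' Solves the approximate normal equations for the SNPs in `snps`
#' simultaneously; the residual variance is
#' `(Syy - b_joint' X'y) / (n_eff - |S| - 1)`.
#'
#' @param ws A [cojo_workspace()].
#' @param snps SNP identifiers to fit jointly.
#' @param kappa_max Condition-number ceiling for X'X.
#' @return data.frame with snp_id, beta, se, pvalue (joint).
#' @export
joint_fit <- function(ws, snps, kappa_max = 1e8) {
  i <- .ws_index(ws, snps)
  p <- length(i)
  R <- ws$R[i, i, drop = FALSE]
  if (p > 1) {
    r2max <- max(R[upper.tri(R)]^2)
    if (r2max > ws$collinearity_r2) {
      off <- which(R^2 > ws$collinearity_r2 & upper.tri(R), arr.ind = TRUE)
      stop("collinear SNPs in joint fit: ",
           paste(apply(off, 1, function(k)
             paste(snps[k[1]], snps[k[2]], sep = "/")), collapse = ", "))
    }
  }
  sD <- sqrt(ws$D[i])
  XtX <- R * tcrossprod(sD)
  Xty <- ws$D[i] * ws$b[i]
  if (kappa(XtX, exact = FALSE) > kappa_max) {
    stop("near-singular X'X in joint fit for SNPs: ",
         paste(snps, collapse = ", "))
  }
  bj <- solve(XtX, Xty)
  df_resid <- ws$n_eff - p - 1
  sigma2 <- (ws$Syy - sum(bj * Xty)) / df_resid
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("negative residual variance: summary data inconsistent with panel")
  }
  se <- sqrt(sigma2 * diag(solve(XtX)))
  data.frame(snp_id = snps, beta = as.vector(bj), se = se,
             pvalue = ztest_p(as.vector(bj), se),
             stringsAsFactors = FALSE)
}

#' Conditional association statistics given a conditioning SNP set
#'
#' For each SNP i outside the conditioning set S, fits `S + {i}` jointly
#' and reports i's coefficient, SE and p-value.  SNPs whose reference r^2
#' with any member of S exceeds the collinearity cutoff are flagged
#' (`collinear = TRUE`) and assigned conditional beta 0 with marginal SE;
#' they are excluded from downstream signal searches.  An empty S returns
#' the marginal statistics.
#'
#' @param ws A [cojo_workspace()].
#' @param conditioning SNP identifiers conditioned upon.
#' @return A `conditional_dataset`: list(conditioning, records, trait_id,
#'   trait_type); `records` has snp_id, beta, se, pvalue, collinear and
#'   excludes the conditioning SNPs.
#' @export
conditional_stats <- function(ws, conditioning = character(0)) {
  rest <- setdiff(ws$snp_id, conditioning)
  if (length(conditioning) == 0L) {
    i <- .ws_index(ws, rest)
    rec <- data.frame(snp_id = rest, beta = ws$b[i], se = ws$se[i],
                      pvalue = ztest_p(ws$b[i], ws$se[i]),
                      collinear = FALSE, stringsAsFactors = FALSE)
  } else {
    iS <- .ws_index(ws, conditioning)
    rec <- do.call(rbind, lapply(rest, function(s) {
      ii <- .ws_index(ws, s)
      r2S <- max(ws$R[ii, iS]^2)
      if (r2S > ws$collinearity_r2) {
        return(data.frame(snp_id = s, beta = 0, se = ws$se[ii], pvalue = 1,
                          collinear = TRUE, stringsAsFactors = FALSE))
      }
      fit <- joint_fit(ws, c(conditioning, s))
      row <- fit[fit$snp_id == s, ]
      data.frame(snp_id = s, beta = row$beta, se = row$se,
                 pvalue = row$pvalue, collinear = FALSE,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(rec) <- NULL
  structure(list(conditioning = conditioning, records = rec,
                 trait_id = ws$trait_id, trait_type = ws$trait_type),
            class = "conditional_dataset")
}

#' @export
as.data.frame.conditional_dataset <- function(x, ...) x$records

#' @export
print.conditional_dataset <- function(x, ...) {
  cat(sprintf("conditional_dataset '%s': %d SNP(s) | conditioning on {%s}\n",
              x$trait_id, nrow(x$records),
              paste(x$conditioning, collapse = ", ")))
  invisible(x)
}

#' Conditional association of one target SNP
#'
#' Convenience wrapper over [conditional_stats()] reporting the target's
#' conditional beta, SE and p given the conditioning set (marginal when
#' the set is empty).
#'
#' @param ws A [cojo_workspace()].
#' @param target_snp SNP of interest (must not be in the conditioning set).
#' @param conditioning SNPs adjusted for.
#' @return List with `beta`, `se`, `pvalue`, `collinear`.
#' @export
conditional_association <- function(ws, target_snp,
                                    conditioning = character(0)) {
  if (target_snp %in% conditioning) {
    stop("target SNP is in the conditioning set")
  }
  if (length(conditioning) == 0L) {
    i <- .ws_index(ws, target_snp)
    return(list(beta = ws$b[i], se = ws$se[i],
                pvalue = ztest_p(ws$b[i], ws$se[i]), collinear = FALSE))
  }
  iS <- .ws_index(ws, conditioning)
  ii <- .ws_index(ws, target_snp)
  if (max(ws$R[ii, iS]^2) > ws$collinearity_r2) {
    return(list(beta = 0, se = ws$se[ii], pvalue = 1, collinear = TRUE))
  }
  fit <- joint_fit(ws, c(conditioning, target_snp))
  row <- fit[fit$snp_id == target_snp, ]
  list(beta = row$beta, se = row$se, pvalue = row$pvalue, collinear = FALSE)
}

# Deterministic ordering: p ascending, |z| descending, snp_id lexical.
.rank_order <- function(p, z, id) order(p, -abs(z), id)

#' Stepwise selection of conditionally independent signals
#'
#' Starts from the minimum-p SNP (if below `p_cutoff`), then repeatedly
#' admits the candidate with the smallest conditional p-value given the
#' current selection (requiring conditional p < `p_cutoff` and maximum
#' r^2 with the selection at or below the collinearity cutoff); after each
#' admission all selected SNPs are refit jointly and any whose joint p
#' rises to `p_cutoff` or above is dropped.  Ties are broken by p, then
#' |z| descending, then snp_id, so the selection is deterministic and
#' independent of input order.
#'
#' @param ws A [cojo_workspace()].
#' @param p_cutoff Significance cutoff (default genome-wide, 5e-8).
#' @param max_iter Safety cap on admission rounds.
#' @return Character vector of selected SNP ids (possibly empty).
#' @export
stepwise_select <- function(ws, p_cutoff = 5e-8, max_iter = 50L) {
  p_marg <- ztest_p(ws$b, ws$se)
  ord <- .rank_order(p_marg, ws$b / ws$se, ws$snp_id)
  if (p_marg[ord[1]] >= p_cutoff) return(character(0))
  selected <- ws$snp_id[ord[1]]
  for (iter in seq_len(max_iter)) {
    cond <- conditional_stats(ws, selected)$records
    cand <- cond[!cond$collinear & cond$pvalue < p_cutoff, , drop = FALSE]
    if (nrow(cand) == 0L) break
    cand <- cand[.rank_order(cand$pvalue, cand$beta / cand$se, cand$snp_id), ]
    admitted <- cand$snp_id[1]
    selected <- c(selected, admitted)
    # backward step: drop selected SNPs that lost joint significance
    repeat {
      jf <- joint_fit(ws, selected)
      worst <- jf[.rank_order(-jf$pvalue, jf$beta / jf$se, jf$snp_id)[1], ]
      if (worst$pvalue < p_cutoff || length(selected) == 1L) break
      selected <- setdiff(selected, worst$snp_id)
    }
  }
  sort(selected)
}
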