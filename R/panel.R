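# Reference genotype panel and pairwise LD (r, r^2, D').
#
# LD r is genotypic: the Pearson correlation of dosage columns, the
# standard when only unphased reference data exist.  D' is computed from
# haplotype frequencies estimated by the classical two-locus EM algorithm
# on unphased genotype counts.

#' Construct a reference genotype panel
#'
#' @param dosages Numeric matrix, individuals x SNPs, entries in `[0, 2]`
#'   (dosage of the counted allele).  Missing dosages are mean-imputed per
#'   SNP.  Column names, if absent, are taken from `alleles$snp_id`.
#' @param alleles data.frame with columns `snp_id`, `counted_allele`,
#'   `other_allele`, one row per SNP in column order.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(dosages, alleles) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(is.data.frame(alleles),
            all(c("snp_id", "counted_allele", "other_allele") %in% names(alleles)),
            nrow(alleles) == ncol(dosages))
  if (is.null(colnames(dosages))) colnames(dosages) <- alleles$snp_id
  if (!identical(colnames(dosages), as.character(alleles$snp_id))) {
    stop("dosage column order does not match alleles$snp_id")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (anyNA(dosages)) {
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) dosages[miss, j] <- mean(dosages[!miss, j])
    }
  }
  structure(list(snp_ids = colnames(dosages),
                 alleles = alleles[c("snp_id", "counted_allele", "other_allele")],
                 dosages = dosages),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs\n",
              nrow(x$dosages), length(x$snp_ids)))
  invisible(x)
}

.panel_col <- function(panel, snp) {
  j <- match(snp, panel$snp_ids)
  if (is.na(j)) stop("SNP not in panel: ", snp)
  x <- panel$dosages[, j]
  if (stats::var(x) == 0) {
    stop("degenerate LD: constant dosage column for SNP ", snp)
  }
  x
}

#' Pairwise LD as signed dosage correlation
#'
#' @param panel A [genotype_panel()].
#' @param snp_a,snp_b SNP identifiers present in the panel.
#' @return Signed Pearson correlation of the two dosage columns.
#' @export
ld_r <- function(panel, snp_a, snp_b) {
  stats::cor(.panel_col(panel, snp_a), .panel_col(panel, snp_b))
}

#' Pairwise LD r-squared
#'
#' @inheritParams ld_r
#' @return Squared dosage correlation in `[0, 1]`.
#' @export
ld_r2 <- function(panel, snp_a, snp_b) {
  ld_r(panel, snp_a, snp_b)^2
}

#' Full LD correlation matrix for a set of panel SNPs
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids SNPs to include (default: all).
#' @return Signed correlation matrix with dimnames `snp_ids`.
#' @export
ld_matrix <- function(panel, snp_ids = panel$snp_ids) {
  j <- match(snp_ids, panel$snp_ids)
  if (anyNA(j)) stop("SNP(s) not in panel: ",
                     paste(snp_ids[is.na(j)], collapse = ", "))
  x <- panel$dosages[, j, drop = FALSE]
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) stop("degenerate LD: constant dosage column(s): ",
                        paste(snp_ids[v == 0], collapse = ", "))
  r <- stats::cor(x)
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

# Two-locus EM on unphased genotype counts.  Genotypes are rounded
# dosages; g1, g2 count the counted allele at each locus.  Haplotypes:
# 11 = both counted, 10, 01, 00.  Only the double heterozygote is phase
# ambiguous.
.em_haplotypes <- function(g1, g2, tol = 1e-8, max_iter = 1000L) {
  g1 <- round(g1); g2 <- round(g2)
  n <- length(g1)
  cnt <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  nm <- function(i, j) cnt[i + 1L, j + 1L]
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  h <- c(h11 = pA * pB, h10 = pA * (1 - pB), h01 = (1 - pA) * pB,
         h00 = (1 - pA) * (1 - pB))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    denom <- h["h11"] * h["h00"] + h["h10"] * h["h01"]
    q <- if (denom > 0) unname(h["h11"] * h["h00"] / denom) else 0.5
    ndh <- nm(1, 1)
    c11 <- 2 * nm(2, 2) + nm(2, 1) + nm(1, 2) + q * ndh
    c10 <- 2 * nm(2, 0) + nm(2, 1) + nm(1, 0) + (1 - q) * ndh
    c01 <- 2 * nm(0, 2) + nm(1, 2) + nm(0, 1) + (1 - q) * ndh
    c00 <- 2 * nm(0, 0) + nm(1, 0) + nm(0, 1) + q * ndh
    h_new <- c(h11 = c11, h10 = c10, h01 = c01, h00 = c00) / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(h = h, converged = converged, iter = iter)
}

#' Pairwise LD D-prime from EM-phased haplotype frequencies
#'
#' Haplotype frequencies are estimated from unphased (rounded) dosages by
#' the standard two-locus EM algorithm started at linkage equilibrium
#' (stopping at max |change| < 1e-8 or 1000 iterations).  With
#' `D = p_AB - p_A p_B`, `D' = |D| / D_max` where
#' `D_max = min(p_A p_b, p_a p_B)` for `D > 0` and
#' `min(p_A p_B, p_a p_b)` for `D < 0`.
#'
#' @inheritParams ld_r
#' @param detail If `TRUE`, also return the haplotype frequencies and D.
#' @return `D'` in `[0, 1]`, or a list when `detail = TRUE`.
#' @export
ld_dprime <- function(panel, snp_a, snp_b, detail = FALSE) {
  g1 <- .panel_col(panel, snp_a)
  g2 <- .panel_col(panel, snp_b)
  em <- .em_haplotypes(g1, g2)
  if (!em$converged) {
    cond <- structure(
      class = c("pqtlmr_em_error", "error", "condition"),
      list(message = sprintf("EM for D' did not converge in %d iterations", em$iter),
           call = sys.call(), estimate = em$h))
    stop(cond)
  }
  h <- em$h
  pA <- unname(h["h11"] + h["h10"]); pB <- unname(h["h11"] + h["h01"])
  D <- unname(h["h11"]) - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax <= 0 || abs(D) < 1e-14) 0 else min(1, abs(D) / dmax)
  if (detail) list(dprime = dprime, D = D, haplotype_freqs = h,
                   iterations = em$iter) else dprime
}

#' Write a genotype panel as dosage matrix + SNP metadata sidecar
#'
#' Produces `<prefix>.dosages.tsv` (individuals x SNPs, header = SNP ids)
#' and `<prefix>.snps.tsv` (snp_id, counted_allele, other_allele).
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  utils::write.table(panel$dosages, paste0(prefix, ".dosages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$alleles, paste0(prefix, ".snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a genotype panel written by [write_panel()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(prefix) {
  dos <- as.matrix(utils::read.table(paste0(prefix, ".dosages.tsv"),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
  snps <- utils::read.table(paste0(prefix, ".snps.tsv"), header = TRUE,
                            sep = "\t", colClasses = "character")
  genotype_panel(dos, snps)
}

#' Import a PLINK .raw-style dosage export
#'
#' Accepts the additive-coding export format: a header of individual-id
#' columns (`FID`, `IID`, `PAT`, `MAT`, `SEX`, `PHENOTYPE`, any subset)
#' followed by one dosage column per SNP named `<snp_id>_<counted allele>`.
#' Other alleles are not recorded in .raw files; supply them via
#' `other_alleles` or they default to `"N"` (sufficient for LD, which does
#' not use alleles).
#'
#' @param path File path (whitespace-delimited with header).
#' @param other_alleles Optional named character vector snp_id -> other allele.
#' @return A [genotype_panel()].
#' @export
read_panel_raw <- function(path, other_alleles = NULL) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE)
  id_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                       names(raw))
  snp_cols <- setdiff(names(raw), id_cols)
  if (length(snp_cols) == 0L) stop("no SNP dosage columns found in ", path)
  m <- regmatches(snp_cols, regexec("^(.*)_([ACGT])$", snp_cols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("column(s) not in <snp_id>_<allele> form: ",
                     paste(snp_cols[bad], collapse = ", "))
  ids <- vapply(m, `[`, "", 2L)
  counted <- vapply(m, `[`, "", 3L)
  oa <- if (is.null(other_alleles)) rep("N", length(ids)) else {
    v <- unname(other_alleles[ids]); v[is.na(v)] <- "N"; v
  }
  alleles <- data.frame(snp_id = ids, counted_allele = counted,
                        other_allele = oa, stringsAsFactors = FALSE)
  dos <- as.matrix(raw[snp_cols])
  colnames(dos) <- ids
  genotype_panel(dos, alleles)
}
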