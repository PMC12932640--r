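# GWAS summary-statistics container and tab-delimited I/O.
#
# A sumstat_table is a data.frame with one validated row per SNP and the
# columns snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
# pvalue, n, plus trait_id / trait_type attributes.  Only biallelic
# single-base SNPs are accepted; indels and multi-allelic records are
# rejected at construction time.

.SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

#' Default file-header to field mapping for summary-statistics files
#'
#' Maps the internal field names to the default tab-delimited header
#' `SNP CHR BP EA OA EAF BETA SE P N`.
#'
#' @return Named character vector (names = internal fields, values = file
#'   column names).
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pvalue = "P", n = "N")
}

#' Construct a validated summary-statistics table
#'
#' Rows violating the record invariants (alleles must be distinct single
#' bases in A/C/G/T, `se > 0`, `0 < eaf < 1`, `0 < pvalue <= 1`,
#' `pos >= 1`, `n >= 1`, unique `snp_id`) are dropped; the rejected rows
#' and their reason codes are kept in the `"rejections"` attribute.
#'
#' @param df data.frame holding the summary-statistic columns.
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param quiet Suppress the rejection-count message.
#' @return A `sumstat_table` (data.frame subclass).
#' @export
sumstat_table <- function(df, trait_id = "trait",
                          trait_type = c("quantitative", "binary"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(.SUMSTAT_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[.SUMSTAT_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- code
  }
  num_bad <- Reduce(`|`, lapply(df[c("pos", "eaf", "beta", "se", "pvalue", "n")],
                                function(x) !is.finite(x)))
  flag(num_bad, "unparsable_numeric")
  flag(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases),
       "not_biallelic_snp")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(df$se <= 0, "se_nonpositive")
  flag(df$eaf <= 0 | df$eaf >= 1, "eaf_out_of_range")
  flag(df$pvalue <= 0 | df$pvalue > 1, "pvalue_out_of_range")
  flag(df$pos < 1, "pos_out_of_range")
  flag(df$n < 1, "n_out_of_range")
  flag(duplicated(df$snp_id), "duplicate_snp_id")

  bad <- !is.na(reason)
  rejections <- data.frame(row = which(bad), snp_id = df$snp_id[bad],
                           reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejections) > 0L && !quiet) {
    message(sprintf("sumstat_table: rejected %d of %d row(s) [%s]",
                    nrow(rejections), nrow(df),
                    paste(unique(rejections$reason), collapse = ", ")))
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$pos <- as.integer(out$pos)
  structure(out,
            trait_id = trait_id, trait_type = trait_type,
            rejections = rejections,
            class = c("sumstat_table", "data.frame"))
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("sumstat_table: trait '%s' (%s), %d SNP(s)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' @param path File path; tab-delimited with a header row.
#' @param column_map Named character vector mapping internal field names to
#'   file column names; see [default_column_map()].
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_id Trait label; defaults to the file name.
#' @param quiet Suppress rejection messages.
#' @return A [sumstat_table()]; rejected rows are recorded in its
#'   `"rejections"` attribute.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          trait_type = c("quantitative", "binary"),
                          trait_id = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  missing_fields <- setdiff(.SUMSTAT_COLS, names(column_map))
  if (length(missing_fields) > 0L) {
    stop("column_map does not cover required field(s): ",
         paste(missing_fields, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "")
  absent <- setdiff(unname(column_map[.SUMSTAT_COLS]), names(raw))
  if (length(absent) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  df <- stats::setNames(raw[unname(column_map[.SUMSTAT_COLS])], .SUMSTAT_COLS)
  tab <- sumstat_table(df, trait_id = trait_id %||% basename(path),
                       trait_type = trait_type, quiet = quiet)
  rej <- attr(tab, "rejections")
  if (nrow(rej) > 0L) {
    # file line number = data row + header line
    rej$line <- rej$row + 1L
    attr(tab, "rejections") <- rej
  }
  tab
}

#' Write a summary-statistics table to a tab-delimited file
#'
#' Columns are written in the fixed default order with full double
#' precision, so `read_sumstats(write_sumstats(x))` is the identity on all
#' fields.
#'
#' @param table A [sumstat_table()].
#' @param path Output path.
#' @param column_map Field-to-header mapping used for the header row.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path, column_map = default_column_map()) {
  stopifnot(inherits(table, "sumstat_table"))
  df <- as.data.frame(table)[.SUMSTAT_COLS]
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  names(df) <- unname(column_map[.SUMSTAT_COLS])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
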