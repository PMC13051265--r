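#' Default column mapping for summary-statistic files
#'
#' Maps the canonical internal field names to the column names expected in
#' delimited summary-statistic files. Override individual entries to read
#' files from other sources, e.g.
#' `sumstatsDialect(variant_id = "rsid", pvalue = "p_value")`.
#'
#' @param ... named overrides of the default mapping (canonical name =
#'   file column name).
#' @return named character vector mapping canonical fields to file columns.
#' @examples
#' sumstatsDialect()
#' sumstatsDialect(variant_id = "MarkerName")
#' @export
sumstatsDialect <- function(...) {
  d <- c(variant_id = "SNP", chrom = "CHR", pos = "POS", ea = "EA", oa = "OA",
         eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P", n = "N")
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(d))
    if (length(bad)) stop("unknown dialect fields: ", paste(bad, collapse = ", "))
    d[names(override)] <- override
  }
  d
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row, renames columns
#' through `dialect`, validates every row and drops invalid rows with a
#' logged reason (nonpositive SE, p-value outside (0,1], effect-allele
#' frequency outside (0,1), malformed alleles, duplicated identifiers --
#' first occurrence wins). Row order is preserved. For binary traits
#' supplied on the odds-ratio scale, set `effectScale = "or"` to convert
#' effects to log-odds at read time.
#'
#' @param path file path.
#' @param trait trait name to attach.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param dialect column mapping, see [sumstatsDialect()].
#' @param effectScale `"beta"` (default) or `"or"` (natural-log converted).
#' @return A [SummaryStats-class] object; the per-row drop log is attached
#'   as attribute `"dropLog"` of the returned object's data.
#' @export
readSumstats <- function(path, trait = basename(path),
                         traitType = c("quantitative", "binary"),
                         dialect = sumstatsDialect(),
                         effectScale = c("beta", "or")) {
  traitType <- match.arg(traitType)
  effectScale <- match.arg(effectScale)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols))
    stop("configuration error: mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  d <- raw[, unname(dialect)]
  names(d) <- names(dialect)
  d$variant_id <- as.character(d$variant_id)
  d$chrom <- as.character(d$chrom)
  d$pos <- as.integer(d$pos)
  d$ea <- toupper(as.character(d$ea))
  d$oa <- toupper(as.character(d$oa))
  for (col in c("eaf", "beta", "se", "pvalue")) d[[col]] <- as.numeric(d[[col]])
  d$n <- as.numeric(d$n)
  if (effectScale == "or") d$beta <- log(d$beta)

  reason <- rep(NA_character_, nrow(d))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(!is.finite(d$beta) | !is.finite(d$se), "missing effect or se")
  flag(is.finite(d$se) & d$se <= 0, "nonpositive se")
  flag(!is.finite(d$pvalue) | d$pvalue <= 0 | d$pvalue > 1, "invalid pvalue")
  flag(!is.na(d$eaf) & (d$eaf <= 0 | d$eaf >= 1), "invalid eaf")
  flag(!(d$ea %in% c("A", "C", "G", "T")) | !(d$oa %in% c("A", "C", "G", "T")) |
         d$ea == d$oa, "invalid alleles")
  flag(duplicated(d$variant_id), "duplicate")

  drop_log <- data.frame(variant_id = d$variant_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  if (nrow(drop_log))
    message("readSumstats: dropped ", nrow(drop_log), " row(s) from ",
            basename(path), " [",
            paste(sprintf("%s: %s", drop_log$variant_id, drop_log$reason),
                  collapse = "; "), "]")
  d <- d[is.na(reason), , drop = FALSE]
  if (nrow(d) == 0) stop("empty-input error: no valid rows in ", path)
  s <- SummaryStats(d, trait = trait, traitType = traitType)
  attr(s@data, "dropLog") <- drop_log
  s
}

#' Write summary statistics as delimited text
#'
#' Inverse of [readSumstats()]: numeric fields are written with 17
#' significant digits so that a write/read round trip reproduces all values
#' exactly.
#'
#' @param s a [SummaryStats-class] object.
#' @param path output file path.
#' @param dialect column mapping used for the header, see
#'   [sumstatsDialect()].
#' @param sep field separator (tab default).
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(s, path, dialect = sumstatsDialect(), sep = "\t") {
  d <- s@data
  out <- data.frame(d$variant_id, d$chrom, d$pos, d$ea, d$oa,
                    sprintf("%.17g", d$eaf), sprintf("%.17g", d$beta),
                    sprintf("%.17g", d$se), sprintf("%.17g", d$pvalue),
                    sprintf("%.17g", d$n))
  names(out) <- unname(dialect)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict summary statistics to a set of variants
#'
#' @param s a [SummaryStats-class] object.
#' @param ids variant identifiers to keep (order of `s` is preserved).
#' @return A [SummaryStats-class] restricted to `ids`.
#' @export
subsetVariants <- function(s, ids) {
  SummaryStats(s@data[s@data$variant_id %in% ids, , drop = FALSE],
               trait = s@trait, traitType = s@traitType)
}

#' Read a labeled LD correlation matrix
#'
#' Expects a delimited square matrix with variant identifiers as both row
#' and column labels, entries in \[-1, 1\] and a unit diagonal (signed r,
#' not r-squared).
#'
#' @param path file path.
#' @return An [LDMatrix-class] object.
#' @export
readLDMatrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  m <- as.matrix(read.delim(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE))
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column labels disagree in ", path)
  LDMatrix(m)
}

#' Write a labeled LD correlation matrix
#'
#' @param ld an [LDMatrix-class] object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(ld, path, sep = "\t") {
  m <- ld@r
  out <- cbind(variant_id = ld@variantIds,
               as.data.frame(apply(m, 2, function(x) sprintf("%.17g", x))))
  names(out) <- c("", ld@variantIds)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
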