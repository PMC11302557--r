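#' @include AllClasses.R
NULL

CANONICAL_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pvalue", "n")
REQUIRED_COLUMNS <- c("variant_id", "effect_allele", "other_allele",
                      "beta", "se", "pvalue")

#' Default column mapping for summary-statistic tables
#'
#' Canonical field name to file column name, matching common GWAS
#' summary-statistic exports. Individual entries can be overridden when a
#' source uses a different dialect.
#'
#' @return named character vector mapping canonical names to header names.
#' @examples
#' defaultColumnMap()
#' @export
defaultColumnMap <- function() {
  c(variant_id = "SNP", chrom = "chr", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pval",
    n = "samplesize")
}

# Validate a raw data.frame of canonical columns; returns list(stats, dropped).
# Only single-base biallelic SNPs survive: indels and multi-allelic codes are
# rejected because the palindrome and strand logic downstream needs single
# bases. Alleles are uppercased; p-values of exactly 0 are replaced by the
# smallest positive double with a warning.
validateRecords <- function(df) {
  for (col in CANONICAL_COLUMNS)
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  df <- df[CANONICAL_COLUMNS]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  zero_p <- !is.na(df$pvalue) & df$pvalue == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " p-value(s) of exactly 0 replaced by the smallest ",
            "positive double")
    df$pvalue[zero_p] <- .Machine$double.xmin
  }

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(df$variant_id) | df$variant_id == "", "missing_id")
  reason <- flag(!(df$effect_allele %in% BASES) |
                 !(df$other_allele %in% BASES), "allele")
  reason <- flag(df$effect_allele == df$other_allele, "allele")
  reason <- flag(is.na(df$beta) | !is.finite(df$beta), "beta")
  reason <- flag(is.na(df$se) | df$se <= 0, "se")
  reason <- flag(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "pvalue")
  reason <- flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf")
  reason <- flag(!is.na(df$n) & df$n <= 0, "n")

  bad <- !is.na(reason)
  dropped <- data.frame(variant_id = df$variant_id[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  stats <- df[!bad, , drop = FALSE]
  rownames(stats) <- NULL
  list(stats = stats, dropped = dropped)
}

#' Construct a SummaryStats object from a data.frame
#'
#' Rows violating the record invariants (non-ACGT or identical alleles,
#' non-positive SE, p-value outside (0, 1], frequency outside (0, 1)) are
#' dropped and tallied in the drop log rather than raising an error.
#'
#' @param df data.frame holding (a subset of) the canonical columns
#'   \code{variant_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pvalue},
#'   \code{n}.
#' @return a \linkS4class{SummaryStats} object.
#' @examples
#' SummaryStats(data.frame(variant_id = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.1, se = 0.01, pvalue = 1e-8))
#' @export
SummaryStats <- function(df) {
  v <- validateRecords(as.data.frame(df))
  new("SummaryStats", stats = v$stats, dropped = v$dropped)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file with one header row, renames columns through
#' \code{columnMap}, validates every row against the record invariants and
#' drops (with a tally) the rows that fail. Row order is preserved.
#'
#' @param path file path.
#' @param columnMap named character vector mapping canonical field names to
#'   file column names; see \code{\link{defaultColumnMap}}. Columns for
#'   \code{variant_id}, alleles, \code{beta}, \code{se} and \code{pvalue}
#'   are required; the rest are optional.
#' @param delimiter field separator, tab by default.
#' @return a \linkS4class{SummaryStats}; dropped rows are available through
#'   \code{droppedRecords()}.
#' @export
readSummaryStats <- function(path, columnMap = defaultColumnMap(),
                             delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty summary-statistic file: ", path)
    return(SummaryStats(data.frame(variant_id = character())))
  }
  map <- defaultColumnMap()
  map[names(columnMap)] <- columnMap
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "")
  missing_req <- setdiff(map[REQUIRED_COLUMNS], names(raw))
  if (length(missing_req))
    stop("mapped column(s) absent from header: ",
         paste(missing_req, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty summary-statistic file: ", path)
    return(SummaryStats(data.frame(variant_id = character())))
  }
  canon <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in CANONICAL_COLUMNS) {
    col <- map[[field]]
    canon[[field]] <- if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA
  }
  SummaryStats(canon)
}

#' Write a summary-statistic table
#'
#' Writes canonical columns under the default header names; absent optional
#' fields become empty cells that read back as absent. Numeric fields are
#' printed with enough digits that \code{readSummaryStats} reproduces the
#' object field-for-field.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @return \code{path}, invisibly.
#' @export
writeSummaryStats <- function(x, path, delimiter = "\t") {
  stopifnot(is(x, "SummaryStats"))
  s <- statsTable(x)
  out <- data.frame(row.names = seq_len(max(nrow(s), 0L)))
  map <- defaultColumnMap()
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", sprintf("%.17g", v))
    else ifelse(is.na(v), "", as.character(v))
  }
  for (field in CANONICAL_COLUMNS) out[[map[[field]]]] <- fmt(s[[field]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Construct an LDMatrix
#'
#' @param m square numeric matrix of squared correlations with variant ids
#'   as dimnames. Asymmetries up to 1e-8 are averaged away; anything larger
#'   is an error.
#' @return an \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("LD matrix must be square")
  if (is.null(rownames(m))) stop("LD matrix must carry variant ids")
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("r2 values must lie in [0, 1]")
  asym <- max(abs(m - t(m)))
  if (asym >= 1e-8) stop("LD matrix asymmetric beyond tolerance (", asym, ")")
  m <- (m + t(m)) / 2
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  diag(m) <- 1
  new("LDMatrix", r2 = m)
}

#' Read a pairwise LD (r2) matrix
#'
#' Expects a delimited file whose first column and header row both carry the
#' variant ids of a square matrix of squared correlations.
#'
#' @param path file path.
#' @param delimiter field separator, tab by default.
#' @return an \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           row.names = 1L, check.names = FALSE)
  LDMatrix(as.matrix(raw))
}

#' Write an LD matrix
#'
#' @param x an \linkS4class{LDMatrix}.
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @return \code{path}, invisibly.
#' @export
writeLDMatrix <- function(x, path, delimiter = "\t") {
  stopifnot(is(x, "LDMatrix"))
  m <- ldValues(x)
  df <- data.frame(variant_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
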