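#' @include AllClasses.R summary-io.R
NULL

subsetStats <- function(x, keep) {
  new("SummaryStats", stats = {
    s <- statsTable(x)[keep, , drop = FALSE]
    rownames(s) <- NULL
    s
  }, dropped = droppedRecords(x))
}

makePartition <- function(x, keep, reason) {
  s <- statsTable(x)
  list(kept = subsetStats(x, keep),
       dropped = data.frame(variant_id = s$variant_id[!keep],
                            reason = rep(reason, sum(!keep)),
                            stringsAsFactors = FALSE))
}

#' Significance screen for instrument candidates
#'
#' Keeps variants whose exposure association p-value is strictly below the
#' threshold; the conventional genome-wide-suggestive 1e-5 cut by default.
#' Boundary values (p exactly equal to the threshold) are dropped.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param threshold p-value cut (default 1e-5).
#' @return list with \code{kept} (a \code{SummaryStats}) and \code{dropped}
#'   (data.frame of \code{variant_id}, \code{reason = "pvalue"}); the two
#'   partition the input.
#' @export
filterByPvalue <- function(x, threshold = 1e-5) {
  stopifnot(is(x, "SummaryStats"))
  makePartition(x, statsTable(x)$pvalue < threshold, "pvalue")
}

#' Minor-allele-frequency screen
#'
#' Computes MAF = min(eaf, 1 - eaf) and keeps variants with MAF at or above
#' the floor. Variants without a frequency are kept with a warning: many
#' summary-statistic exports omit allele frequency, and rejecting them
#' outright would empty such inputs.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param mafMin MAF floor (default 0.01).
#' @return list with \code{kept} and \code{dropped} (\code{reason = "maf"}).
#' @export
filterByMaf <- function(x, mafMin = 0.01) {
  stopifnot(is(x, "SummaryStats"))
  eaf <- statsTable(x)$eaf
  maf <- pmin(eaf, 1 - eaf)
  if (anyNA(eaf) && nrow(statsTable(x)))
    warning(sum(is.na(eaf)), " variant(s) without eaf kept unscreened by MAF")
  makePartition(x, is.na(maf) | maf >= mafMin, "maf")
}

#' Instrument-strength F statistic
#'
#' The single-SNP approximation F = (beta/se)^2 (the squared Wald z) by
#' default; alternatively the R-squared form R2(N-2)/(1-R2), with R2 the
#' variance explained by the variant assuming standardized traits, which
#' needs \code{eaf} and \code{n}.
#'
#' @param x a \linkS4class{SummaryStats} (or data.frame with the same
#'   columns).
#' @param method "wald" (default) or "r2".
#' @return numeric vector of F statistics, named by variant id.
#' @examples
#' s <- SummaryStats(data.frame(variant_id = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.05, se = 0.005, pvalue = 1e-8))
#' fStatistic(s)  # (0.05 / 0.005)^2 = 100
#' @export
fStatistic <- function(x, method = c("wald", "r2")) {
  method <- match.arg(method)
  s <- if (is(x, "SummaryStats")) statsTable(x) else x
  f <- if (method == "wald") {
    (s$beta / s$se)^2
  } else {
    if (anyNA(s$eaf) || anyNA(s$n))
      stop("r2-based F needs eaf and n for every variant")
    v <- 2 * s$eaf * (1 - s$eaf)
    r2 <- v * s$beta^2 / (v * s$beta^2 + v * s$se^2 * s$n)
    r2 * (s$n - 2) / (1 - r2)
  }
  stats::setNames(f, s$variant_id)
}

#' Weak-instrument screen
#'
#' Drops variants whose F statistic falls below the floor (conventionally
#' 10, under which weak-instrument bias is assumed).
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param fMin F floor (default 10).
#' @param method F formula passed to \code{\link{fStatistic}}.
#' @return list with \code{kept}, \code{dropped} (\code{reason = "weak"})
#'   and \code{fStats} (named numeric for the input variants).
#' @export
filterByFStat <- function(x, fMin = 10, method = "wald") {
  stopifnot(is(x, "SummaryStats"))
  f <- fStatistic(x, method)
  out <- makePartition(x, f >= fMin, "weak")
  out$fStats <- f
  out
}

#' Greedy LD clumping
#'
#' Standard greedy procedure: candidates are ranked by ascending p-value;
#' the best remaining variant becomes an index SNP and every remaining
#' variant on the same chromosome within \code{windowKb} of it with
#' r2 >= \code{r2Max} against it is dropped. Variants without positions are
#' treated as always within the window. Without an LD matrix the step is a
#' no-op: every variant is retained and a prominent warning is raised,
#' since computing LD from a reference panel is outside this package.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param ld an \linkS4class{LDMatrix} covering all variants, or NULL.
#' @param r2Max clumping threshold (default 0.01).
#' @param windowKb window half-width in kilobases (default 10000).
#' @return list with \code{kept} and \code{dropped} (\code{reason =
#'   "clumped"}).
#' @export
ldClump <- function(x, ld = NULL, r2Max = 0.01, windowKb = 10000) {
  stopifnot(is(x, "SummaryStats"))
  s <- statsTable(x)
  if (is.null(ld)) {
    warning("no LD matrix supplied: clumping skipped, all ",
            nrow(s), " variants retained")
    return(makePartition(x, rep(TRUE, nrow(s)), "clumped"))
  }
  stopifnot(is(ld, "LDMatrix"))
  r2 <- ldValues(ld)
  missing_ids <- setdiff(s$variant_id, rownames(r2))
  if (length(missing_ids))
    stop("variant(s) absent from LD matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  remaining <- order(s$pvalue, s$variant_id)
  keep <- logical(nrow(s))
  while (length(remaining)) {
    idx <- remaining[1L]
    keep[idx] <- TRUE
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    within <- withinWindow(s, idx, remaining, windowKb)
    linked <- r2[s$variant_id[idx], s$variant_id[remaining]] >= r2Max
    remaining <- remaining[!(within & linked)]
  }
  makePartition(x, keep, "clumped")
}

withinWindow <- function(s, idx, others, windowKb) {
  posKnown <- !is.na(s$pos[idx]) & !is.na(s$pos[others])
  sameChrom <- is.na(s$chrom[idx]) | is.na(s$chrom[others]) |
    s$chrom[idx] == s$chrom[others]
  close <- abs(s$pos[others] - s$pos[idx]) <= windowKb * 1000
  ifelse(posKnown, sameChrom & close, TRUE)
}

#' Full instrument-selection pass
#'
#' Applies the screens in order: significance (p < \code{pvalThreshold}),
#' MAF, LD clumping, then the F-statistic screen. Independent screens
#' commute, so the order only affects which reason a doubly-failing variant
#' is logged under.
#'
#' @param x a \linkS4class{SummaryStats} of exposure associations.
#' @param ld optional \linkS4class{LDMatrix} for clumping.
#' @param pvalThreshold significance cut (default 1e-5).
#' @param mafMin MAF floor (default 0.01).
#' @param fMin F floor (default 10).
#' @param r2Max,windowKb clumping parameters (defaults 0.01 and 10000).
#' @return list with \code{kept} (a \code{SummaryStats}), \code{dropLog}
#'   (data.frame \code{variant_id}, \code{reason}; one row per dropped
#'   variant) and \code{fStats} (for the variants reaching the F screen).
#' @export
selectInstruments <- function(x, ld = NULL, pvalThreshold = 1e-5,
                              mafMin = 0.01, fMin = 10, r2Max = 0.01,
                              windowKb = 10000) {
  p1 <- filterByPvalue(x, pvalThreshold)
  p2 <- filterByMaf(p1$kept, mafMin)
  p3 <- ldClump(p2$kept, ld, r2Max, windowKb)
  p4 <- filterByFStat(p3$kept, fMin)
  list(kept = p4$kept,
       dropLog = rbind(p1$dropped, p2$dropped, p3$dropped, p4$dropped),
       fStats = p4$fStats)
}
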