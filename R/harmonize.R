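#' @include AllClasses.R
NULL

# Keep the smallest-p record per variant id, logging the rest as duplicates.
dedupeStats <- function(s) {
  ord <- order(s$pvalue, seq_len(nrow(s)))
  s2 <- s[ord, , drop = FALSE]
  dup <- duplicated(s2$variant_id)
  list(stats = s2[!dup, , drop = FALSE],
       dupes = s2$variant_id[dup])
}

#' Align exposure and outcome records to a shared effect allele
#'
#' Matches variants by id and reconciles allele coding so both effect sizes
#' refer to the same effect allele. Palindromic variants (A/T or C/G allele
#' pairs) are excluded unconditionally, since their strand cannot be
#' resolved from alleles alone. For the rest: identical outcome alleles are
#' copied as-is; swapped alleles negate the outcome beta and reflect its
#' frequency; strand-complemented alleles are relabeled with the sign
#' preserved; complemented-and-swapped alleles are relabeled and negated;
#' anything else is excluded as unmatched. Duplicate ids within one table
#' keep the smallest-p instance.
#'
#' @param exposure,outcome \linkS4class{SummaryStats} objects.
#' @return a \linkS4class{HarmonizedSet}; \code{exclusionLog()} lists every
#'   excluded variant with reason \code{palindrome}, \code{unmatched},
#'   \code{missing} or \code{duplicate}.
#' @examples
#' ex <- SummaryStats(data.frame(variant_id = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.1, se = 0.01, pvalue = 1e-8))
#' out <- SummaryStats(data.frame(variant_id = "rs1", effect_allele = "G",
#'   other_allele = "A", beta = 0.05, se = 0.02, pvalue = 0.01))
#' harmonizedTable(harmonize(ex, out))  # by is -0.05: alleles were swapped
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  dx <- dedupeStats(statsTable(exposure))
  dy <- dedupeStats(statsTable(outcome))
  ex <- dx$stats
  oy <- dy$stats

  excl <- data.frame(variant_id = c(dx$dupes, dy$dupes),
                     reason = rep("duplicate", length(dx$dupes) + length(dy$dupes)),
                     stringsAsFactors = FALSE)

  onlyOne <- c(setdiff(ex$variant_id, oy$variant_id),
               setdiff(oy$variant_id, ex$variant_id))
  if (length(onlyOne))
    excl <- rbind(excl, data.frame(variant_id = onlyOne, reason = "missing",
                                   stringsAsFactors = FALSE))

  shared <- intersect(ex$variant_id, oy$variant_id)
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  oy <- oy[match(shared, oy$variant_id), , drop = FALSE]

  ea <- ex$effect_allele; oa <- ex$other_allele
  ea2 <- oy$effect_allele; oa2 <- oy$other_allele
  cea <- COMPLEMENT[ea]; coa <- COMPLEMENT[oa]

  pal <- isPalindromic(ea, oa)
  same <- ea2 == ea & oa2 == oa
  swap <- ea2 == oa & oa2 == ea
  flip <- ea2 == cea & oa2 == coa
  flipswap <- ea2 == coa & oa2 == cea

  keep <- !pal & (same | swap | flip | flipswap)
  reason <- ifelse(pal, "palindrome",
                   ifelse(same | swap | flip | flipswap, NA, "unmatched"))
  if (any(!keep))
    excl <- rbind(excl, data.frame(variant_id = shared[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE))

  sgn <- ifelse(swap | flipswap, -1, 1)
  snps <- data.frame(variant_id = shared,
                     bx = ex$beta, sx = ex$se,
                     by = sgn * oy$beta, sy = oy$se,
                     eaf_x = ex$eaf,
                     eaf_y = ifelse(sgn < 0, 1 - oy$eaf, oy$eaf),
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(snps) <- NULL
  rownames(excl) <- NULL
  new("HarmonizedSet", snps = snps, exclusions = excl)
}

#' Construct a HarmonizedSet directly from aligned effect estimates
#'
#' Convenience constructor for already-aligned instrument sets, used by the
#' estimators' examples and tests.
#'
#' @param variant_id character vector (defaults to rs1..rsJ).
#' @param bx,sx exposure effects and standard errors.
#' @param by,sy outcome effects and standard errors.
#' @param eaf_x,eaf_y optional aligned allele frequencies.
#' @return a \linkS4class{HarmonizedSet} with an empty exclusion log.
#' @export
harmonizedSet <- function(bx, by, sx, sy,
                          variant_id = sprintf("rs%d", seq_along(bx)),
                          eaf_x = NA_real_, eaf_y = NA_real_) {
  snps <- data.frame(variant_id = variant_id, bx = bx, sx = sx, by = by,
                     sy = sy, eaf_x = eaf_x, eaf_y = eaf_y,
                     stringsAsFactors = FALSE)
  new("HarmonizedSet", snps = snps, exclusions = emptyDropLog())
}

subsetHarmonized <- function(h, keep) {
  s <- harmonizedTable(h)[keep, , drop = FALSE]
  rownames(s) <- NULL
  new("HarmonizedSet", snps = s, exclusions = exclusionLog(h))
}
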