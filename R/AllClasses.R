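#' @import methods
NULL

#' GWAS summary statistics for one trait
#'
#' Validated per-variant association statistics from a single GWAS: variant
#' identifier, alleles, effect-allele frequency, effect size (log odds for
#' binary traits), standard error, p-value and sample size. Rows failing
#' validation at construction are dropped and recorded in the drop log.
#'
#' @slot stats data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pvalue}, \code{n}. \code{chrom},
#'   \code{pos}, \code{eaf} and \code{n} may be \code{NA}.
#' @slot dropped data.frame with columns \code{variant_id} and \code{reason}
#'   recording rows rejected at validation.
#' @export
setClass("SummaryStats",
  representation(stats = "data.frame", dropped = "data.frame"))

setValidity("SummaryStats", function(object) {
  s <- object@stats
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) == 0L) return(TRUE)
  bases <- c("A", "C", "G", "T")
  if (!all(s$effect_allele %in% bases) || !all(s$other_allele %in% bases))
    return("alleles must be single bases A/C/G/T")
  if (any(s$effect_allele == s$other_allele))
    return("effect and other allele must differ")
  if (any(!is.finite(s$se)) || any(s$se <= 0)) return("se must be > 0")
  if (any(!is.finite(s$pvalue)) || any(s$pvalue <= 0 | s$pvalue > 1))
    return("pvalue must lie in (0, 1]")
  ok_eaf <- is.na(s$eaf) | (s$eaf > 0 & s$eaf < 1)
  if (!all(ok_eaf)) return("eaf must lie in (0, 1) when present")
  TRUE
})

#' Pairwise linkage-disequilibrium matrix
#'
#' Symmetric matrix of squared allelic correlations (r2) with unit diagonal,
#' indexed by variant identifier.
#'
#' @slot r2 numeric matrix; symmetric, diagonal 1, entries in [0, 1],
#'   dimnames give the variant identifiers.
#' @export
setClass("LDMatrix", representation(r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("r2 matrix must carry variant ids as dimnames")
  if (nrow(m) != ncol(m)) return("r2 matrix must be square")
  if (!identical(rownames(m), colnames(m)))
    return("row and column ids must agree")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    return("r2 entries must lie in [0, 1]")
  if (any(abs(diag(m) - 1) > 1e-8)) return("diagonal must be 1")
  if (max(abs(m - t(m))) > 1e-8) return("r2 matrix must be symmetric")
  TRUE
})

#' Exposure/outcome instrument set on a shared effect allele
#'
#' One row per instrument after allele harmonization: exposure effect
#' \code{bx} with standard error \code{sx}, outcome effect \code{by} with
#' standard error \code{sy}, both expressed per copy of the same effect
#' allele, plus aligned allele frequencies where available.
#'
#' @slot snps data.frame with columns \code{variant_id}, \code{bx},
#'   \code{sx}, \code{by}, \code{sy}, \code{eaf_x}, \code{eaf_y}.
#' @slot exclusions data.frame with columns \code{variant_id},
#'   \code{reason} (palindrome, unmatched, missing, duplicate).
#' @export
setClass("HarmonizedSet",
  representation(snps = "data.frame", exclusions = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  s <- object@snps
  need <- c("variant_id", "bx", "sx", "by", "sy", "eaf_x", "eaf_y")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) > 0L && (any(s$sx <= 0) || any(s$sy <= 0)))
    return("sx and sy must be > 0")
  TRUE
})

#' A single causal-effect estimate
#'
#' One method's causal estimate on the log scale together with its standard
#' error, p-value, and the odds-ratio conversion with 95% confidence bounds.
#'
#' @slot method character; one of wald, ivw, egger_slope, egger_intercept,
#'   weighted_median, simple_mode, weighted_mode.
#' @slot nSnp integer; number of instruments used.
#' @slot beta,se,pvalue numeric; estimate (log odds of outcome per unit
#'   exposure), standard error, two-sided p-value.
#' @slot or,ciLow,ciHigh numeric; exp(beta) and the 95% interval on the
#'   odds-ratio scale.
#' @slot details list; method-specific extras (e.g. the fixed-effect SE and
#'   Cochran Q for the inverse-variance weighted estimator).
#' @export
setClass("MREstimate",
  representation(method = "character", nSnp = "integer", beta = "numeric",
                 se = "numeric", pvalue = "numeric", or = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", details = "list"))

setValidity("MREstimate", function(object) {
  if (length(object@beta) != 1L || length(object@se) != 1L)
    return("beta and se must be scalars")
  if (!is.finite(object@beta) || !is.finite(object@se) || object@se < 0)
    return("beta must be finite and se >= 0")
  if (object@pvalue <= 0 || object@pvalue > 1) return("pvalue must lie in (0, 1]")
  if (abs(object@or - exp(object@beta)) > 1e-12 * max(1, object@or))
    return("or must equal exp(beta)")
  if (object@se > 0 && !(object@ciLow < object@or && object@or < object@ciHigh))
    return("ci must bracket the odds ratio when se > 0")
  TRUE
})

setClassUnion("MREstimateOrNULL", c("MREstimate", "NULL"))

#' Cochran heterogeneity test result
#'
#' @slot Q numeric; weighted sum of squared deviations from the reference fit.
#' @slot df integer; J - 1 about the IVW estimate, J - 2 about the Egger line.
#' @slot pvalue numeric; upper-tail chi-square probability.
#' @export
setClass("HeterogeneityResult",
  representation(Q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  if (object@Q < 0) return("Q must be >= 0")
  if (object@pvalue <= 0 || object@pvalue > 1) return("pvalue must lie in (0, 1]")
  TRUE
})

#' MR-PRESSO pleiotropy test result
#'
#' Global residual-sum-of-squares test, per-SNP outlier p-values
#' (Bonferroni-adjusted), the ordered list of instruments removed by the
#' iterative loop, and the outlier-corrected IVW estimate.
#'
#' @slot globalRSS numeric; observed weighted residual sum of squares.
#' @slot globalP numeric; empirical p with the add-one rule, so at least
#'   1/(nSim + 1).
#' @slot outlierPvalues named numeric; Bonferroni-adjusted per-SNP empirical
#'   p-values from the final iteration.
#' @slot removedIds character; instruments removed, in removal order.
#' @slot correctedEstimate MREstimate or NULL; IVW on the surviving set.
#' @slot nSim,seed integer; simulation count and RNG seed.
#' @export
setClass("PressoResult",
  representation(globalRSS = "numeric", globalP = "numeric",
                 outlierPvalues = "numeric", removedIds = "character",
                 correctedEstimate = "MREstimateOrNULL",
                 nSim = "integer", seed = "integer"))

setValidity("PressoResult", function(object) {
  if (object@globalP < 1 / (object@nSim + 1) - 1e-12 || object@globalP > 1)
    return("globalP must lie in [1/(nSim+1), 1]")
  TRUE
})

#' Generative parameters for a synthetic exposure/outcome pair
#'
#' Ground-truth parameters of the bundled summary-statistic generator. The
#' defaults describe a study with strong instruments (resampled to clear the
#' relevance screen), no pleiotropy and no outliers; every departure from
#' validity is switched on explicitly.
#'
#' @slot J integer; number of instruments.
#' @slot causalEffect numeric; true effect of exposure on outcome.
#' @slot bxSd numeric; SD of true per-allele exposure effects.
#' @slot seX,seY numeric; sampling SE of exposure/outcome effect estimates
#'   (scalar or length J). A value of 0 means noise-free observation (the
#'   emitted records carry a tiny positive SE so downstream weights exist).
#' @slot invalidFraction numeric in [0,1]; share of SNPs given pleiotropy.
#' @slot pleioMean,pleioSd numeric; mean/SD of the pleiotropic effects of
#'   invalid SNPs (directional when pleioMean != 0).
#' @slot corPleio numeric; coefficient linking pleiotropy to instrument
#'   strength (alpha = corPleio * bx + noise); 0 preserves InSIDE.
#' @slot outlierIds integer; indices receiving an extra pleiotropic shift.
#' @slot outlierShift numeric; size of that shift.
#' @slot palindromeFraction numeric in [0,1]; share of SNPs assigned A/T or
#'   C/G allele pairs.
#' @slot eafRange numeric length 2 within (0.01, 0.99); uniform sampling
#'   interval for effect-allele frequency.
#' @slot ldBlocks list of c(size, r2) pairs for the companion LD matrix;
#'   empty means all variants independent.
#' @slot nExposure,nOutcome integer; GWAS sample sizes written to records.
#' @slot seed integer; RNG seed, fixing the output bitwise.
#' @export
setClass("TruthParams",
  representation(J = "integer", causalEffect = "numeric", bxSd = "numeric",
                 seX = "numeric", seY = "numeric",
                 invalidFraction = "numeric", pleioMean = "numeric",
                 pleioSd = "numeric", corPleio = "numeric",
                 outlierIds = "integer", outlierShift = "numeric",
                 palindromeFraction = "numeric", eafRange = "numeric",
                 ldBlocks = "list", nExposure = "integer",
                 nOutcome = "integer", seed = "integer"))

setValidity("TruthParams", function(object) {
  if (object@J < 1L) return("J must be >= 1")
  if (object@bxSd <= 0) return("bxSd must be > 0")
  if (any(object@seX < 0) || any(object@seY < 0)) return("seX and seY must be >= 0")
  if (!length(object@seX) %in% c(1L, object@J) ||
      !length(object@seY) %in% c(1L, object@J))
    return("seX and seY must be scalar or length J")
  fr <- c(object@invalidFraction, object@palindromeFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (length(object@eafRange) != 2L || object@eafRange[1] <= 0.01 ||
      object@eafRange[2] >= 0.99 || object@eafRange[1] >= object@eafRange[2])
    return("eafRange must be an increasing interval within (0.01, 0.99)")
  if (any(object@outlierIds < 1L | object@outlierIds > object@J))
    return("outlierIds must index 1..J")
  TRUE
})

#' Synthetic exposure/outcome pair with realized ground truth
#'
#' @slot exposure,outcome SummaryStats sharing variant ids and allele pairs.
#' @slot truth list recording the TruthParams plus every realized per-SNP
#'   quantity: \code{bxTrue}, \code{alpha}, \code{invalidIdx},
#'   \code{outlierIds}, \code{palindromeIdx}.
#' @export
setClass("SyntheticPair",
  representation(exposure = "SummaryStats", outcome = "SummaryStats",
                 truth = "list"))

setValidity("SyntheticPair", function(object) {
  if (!identical(object@exposure@stats$variant_id,
                 object@outcome@stats$variant_id))
    return("exposure and outcome must share variant ids")
  if (!all(c("bxTrue", "alpha") %in% names(object@truth)))
    return("truth must record bxTrue and alpha")
  TRUE
})

#' Result of one exposure/outcome MR analysis
#'
#' @slot exposureLabel,outcomeLabel character; e.g. taxon name plus rank,
#'   and the disease outcome.
#' @slot status character; "ok" or "insufficient_instruments".
#' @slot estimates list of MREstimate keyed by method (post outlier removal
#'   when MR-PRESSO removed instruments).
#' @slot estimatesPre list; the pre-removal estimates when removal occurred,
#'   else empty.
#' @slot sensitivity list; heterogeneity, Egger-intercept, MR-PRESSO and
#'   leave-one-out components.
#' @slot nSnpInitial,nSnpFinal integer; instrument counts before selection
#'   and in the final estimates.
#' @slot dropLog data.frame; per-variant drop/exclusion reasons from every
#'   stage.
#' @export
setClass("PairResult",
  representation(exposureLabel = "character", outcomeLabel = "character",
                 status = "character", estimates = "list",
                 estimatesPre = "list", sensitivity = "list",
                 nSnpInitial = "integer", nSnpFinal = "integer",
                 dropLog = "data.frame"))

setValidity("PairResult", function(object) {
  if (object@nSnpFinal > object@nSnpInitial)
    return("nSnpFinal cannot exceed nSnpInitial")
  TRUE
})

#' Study-level summary of IVW findings
#'
#' @slot counts data.frame; per-outcome counts of IVW-significant pairs
#'   split by direction (odds ratio above vs below 1).
#' @slot totalSignificant integer; grand total of significant pairs.
#' @slot bonferroni data.frame; per taxonomic rank, the number of taxa and
#'   the 0.05/n threshold.
#' @slot survivors data.frame; pairs whose IVW p-value clears the rank-level
#'   Bonferroni threshold.
#' @export
setClass("StudySummary",
  representation(counts = "data.frame", totalSignificant = "integer",
                 bonferroni = "data.frame", survivors = "data.frame"))

setValidity("StudySummary", function(object) {
  cnt <- object@counts
  if (nrow(cnt) && any(cnt$positive + cnt$negative != cnt$total))
    return("positive + negative must equal total per outcome")
  TRUE
})
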