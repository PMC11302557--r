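#' @include AllClasses.R summary-io.R
NULL

# z threshold a true effect must clear so its observed association passes the
# genome-wide-suggestive screen (p < 1e-5, |z| > 4.417) with high probability:
# the instrument pool emulates a pre-selected set of relevant SNPs.
RELEVANCE_Z_FLOOR <- stats::qnorm(1 - 5e-6) + 2

#' Ground-truth parameters for the synthetic GWAS generator
#'
#' Builds a validated \linkS4class{TruthParams}. The defaults describe the
#' simulation conditions used throughout the package's tests: J strong,
#' independent instruments measured with exposure-side SE 0.005 and
#' outcome-side SE 0.05, no pleiotropy, no outliers, no palindromic
#' variants, effect-allele frequencies uniform on (0.05, 0.95), and GWAS
#' sample sizes typical of a microbiome meta-GWAS exposure (~18,000) and a
#' biobank outcome (~450,000).
#'
#' @param J number of instruments (default 30).
#' @param causalEffect true effect of exposure on outcome (default 0).
#' @param bxSd SD of true exposure effects (default 0.1).
#' @param seX,seY sampling SEs of the exposure/outcome effect estimates,
#'   scalar or length J (defaults 0.005 and 0.05). Zero means noise-free.
#' @param invalidFraction share of SNPs given a pleiotropic effect.
#' @param pleioMean,pleioSd mean and SD of those pleiotropic effects.
#' @param corPleio coefficient linking pleiotropy to instrument strength
#'   (alpha = corPleio * bx + noise); default 0 keeps InSIDE intact.
#' @param outlierIds indices of SNPs receiving an extra pleiotropic shift.
#' @param outlierShift size of that shift (default 10 x max outcome SE,
#'   i.e. a ten-sigma outlier).
#' @param palindromeFraction share of SNPs assigned A/T or C/G alleles.
#' @param eafRange uniform sampling interval for effect-allele frequency.
#' @param ldBlocks list of \code{c(size, r2)} pairs describing block-diagonal
#'   LD for \code{simulateLD}; empty means independence.
#' @param nExposure,nOutcome GWAS sample sizes written to the records.
#' @param seed integer seed; fixing it makes the output bitwise reproducible.
#' @return a \linkS4class{TruthParams}.
#' @examples
#' truthParams(J = 10, causalEffect = 0.5, seed = 7)
#' @export
truthParams <- function(J = 30L, causalEffect = 0, bxSd = 0.1,
                        seX = 0.005, seY = 0.05,
                        invalidFraction = 0, pleioMean = 0, pleioSd = 0,
                        corPleio = 0, outlierIds = integer(0),
                        outlierShift = 10 * max(seY),
                        palindromeFraction = 0,
                        eafRange = c(0.05, 0.95), ldBlocks = list(),
                        nExposure = 18340L, nOutcome = 450000L, seed = 1L) {
  new("TruthParams", J = as.integer(J), causalEffect = causalEffect,
      bxSd = bxSd, seX = seX, seY = seY,
      invalidFraction = invalidFraction, pleioMean = pleioMean,
      pleioSd = pleioSd, corPleio = corPleio,
      outlierIds = as.integer(outlierIds), outlierShift = outlierShift,
      palindromeFraction = palindromeFraction, eafRange = eafRange,
      ldBlocks = ldBlocks, nExposure = as.integer(nExposure),
      nOutcome = as.integer(nOutcome), seed = as.integer(seed))
}

# non-palindromic ordered allele pairs (effect, other)
NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                 "G","A", "G","T", "T","C", "T","G"),
                               ncol = 2L, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                            ncol = 2L, byrow = TRUE)

#' Simulate an exposure/outcome summary-statistic pair with known truth
#'
#' Generates, for each SNP j: a true exposure effect bx_j ~ N(0, bxSd^2)
#' resampled until it clears the relevance floor (so that the observed
#' association passes the p < 1e-5 screen with high probability); an
#' observed exposure effect N(bx_j, seX^2); a true outcome effect
#' causalEffect * bx_j + alpha_j, where alpha_j is 0 for valid SNPs and,
#' for the invalid fraction, drawn N(pleioMean + corPleio * |bx_j|,
#' pleioSd^2) on the exposure-increasing allele orientation (so directional
#' pleiotropy means what MR-Egger's intercept measures), plus
#' \code{outlierShift} on the same orientation for planted outliers; and an
#' observed outcome effect
#' N(., seY^2). P-values are two-sided normal; alleles are non-palindromic
#' except for the requested palindromic fraction; frequencies are uniform on
#' \code{eafRange} and shared between the two GWAS.
#'
#' @param truth a \linkS4class{TruthParams}.
#' @return a \linkS4class{SyntheticPair}; \code{truthValues()} exposes every
#'   realized per-SNP quantity (\code{bxTrue}, \code{alpha},
#'   \code{invalidIdx}, \code{outlierIds}, \code{palindromeIdx}).
#' @examples
#' pair <- simulatePair(truthParams(J = 5, causalEffect = 0.3, seed = 2))
#' truthValues(pair)$bxTrue
#' @export
simulatePair <- function(truth) {
  stopifnot(is(truth, "TruthParams"))
  validObject(truth)
  J <- truth@J
  seX <- rep_len(truth@seX, J)
  seY <- rep_len(truth@seY, J)

  withSeed(truth@seed, {
    # true exposure effects above the relevance floor
    floorAbs <- ifelse(seX > 0, RELEVANCE_Z_FLOOR * seX, 0)
    bxTrue <- stats::rnorm(J, 0, truth@bxSd)
    for (it in seq_len(1000L)) {
      weak <- abs(bxTrue) <= floorAbs
      if (!any(weak)) break
      bxTrue[weak] <- stats::rnorm(sum(weak), 0, truth@bxSd)
    }

    # pleiotropy is defined on the exposure-increasing allele orientation
    # (the orientation MR-Egger adopts), so a nonzero pleioMean shifts the
    # Egger intercept by exactly that amount
    orient <- sign(bxTrue)
    nInvalid <- round(truth@invalidFraction * J)
    invalidIdx <- if (nInvalid > 0) sort(sample.int(J, nInvalid)) else integer(0)
    alpha <- numeric(J)
    if (nInvalid > 0)
      alpha[invalidIdx] <- orient[invalidIdx] *
        (truth@pleioMean + truth@corPleio * abs(bxTrue[invalidIdx]) +
         stats::rnorm(nInvalid, 0, truth@pleioSd))
    if (length(truth@outlierIds))
      alpha[truth@outlierIds] <- alpha[truth@outlierIds] +
        orient[truth@outlierIds] * truth@outlierShift

    byTrue <- truth@causalEffect * bxTrue + alpha
    bxObs <- bxTrue + if (all(seX == 0)) 0 else stats::rnorm(J, 0, seX)
    byObs <- byTrue + if (all(seY == 0)) 0 else stats::rnorm(J, 0, seY)

    nPal <- round(truth@palindromeFraction * J)
    palindromeIdx <- if (nPal > 0) sort(sample.int(J, nPal)) else integer(0)
    alleles <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), J,
                                               replace = TRUE), , drop = FALSE]
    if (nPal > 0)
      alleles[palindromeIdx, ] <-
        PALINDROMIC_PAIRS[sample.int(nrow(PALINDROMIC_PAIRS), nPal,
                                     replace = TRUE), , drop = FALSE]

    eaf <- stats::runif(J, truth@eafRange[1], truth@eafRange[2])

    # positions: blocks (when given) sit tightly together and far from other
    # blocks, so the clumping window sees within-block pairs as neighbours
    blockOf <- blockIndex(truth)
    pos <- 1e6 + (blockOf - 1) * 2e7 + stats::ave(blockOf, blockOf,
                                                  FUN = seq_along) * 1e4

    # records need a strictly positive SE; a noise-free simulation keeps the
    # zero-noise betas but writes a vanishingly small SE
    seXrec <- ifelse(seX > 0, seX, 1e-8)
    seYrec <- ifelse(seY > 0, seY, 1e-8)
    ids <- sprintf("rs%d", seq_len(J))
    mk <- function(beta, se, n) data.frame(
      variant_id = ids, chrom = "1", pos = pos,
      effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
      eaf = eaf, beta = beta, se = se,
      pvalue = twoSidedNormalP(beta / se), n = n,
      stringsAsFactors = FALSE)
    exposure <- SummaryStats(mk(bxObs, seXrec, truth@nExposure))
    outcome <- SummaryStats(mk(byObs, seYrec, truth@nOutcome))

    new("SyntheticPair", exposure = exposure, outcome = outcome,
        truth = list(params = truth, bxTrue = bxTrue, alpha = alpha,
                     byTrue = byTrue, invalidIdx = invalidIdx,
                     outlierIds = truth@outlierIds,
                     palindromeIdx = palindromeIdx,
                     causalEffect = truth@causalEffect))
  })
}

blockIndex <- function(truth) {
  J <- truth@J
  if (!length(truth@ldBlocks)) return(seq_len(J))
  sizes <- vapply(truth@ldBlocks, function(b) as.integer(b[1]), integer(1))
  if (sum(sizes) != J) stop("ldBlocks sizes must sum to J")
  rep(seq_along(sizes), sizes)
}

#' Simulate the block-diagonal LD matrix implied by TruthParams
#'
#' @param truth a \linkS4class{TruthParams} with non-empty \code{ldBlocks};
#'   each element is \code{c(size, r2)}. Block sizes must sum to J.
#' @return an \linkS4class{LDMatrix}: within-block off-diagonals equal the
#'   block's r2, across blocks 0, diagonal 1. Ids match
#'   \code{simulatePair}'s.
#' @export
simulateLD <- function(truth) {
  stopifnot(is(truth, "TruthParams"))
  if (!length(truth@ldBlocks)) stop("ldBlocks must be given")
  blockOf <- blockIndex(truth)
  r2s <- vapply(truth@ldBlocks, function(b) as.numeric(b[2]), numeric(1))
  J <- truth@J
  m <- matrix(0, J, J)
  for (b in seq_along(r2s)) {
    idx <- which(blockOf == b)
    m[idx, idx] <- r2s[b]
  }
  diag(m) <- 1
  ids <- sprintf("rs%d", seq_len(J))
  dimnames(m) <- list(ids, ids)
  LDMatrix(m)
}
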