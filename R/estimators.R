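#' @include AllClasses.R harmonize.R
NULL

#' Odds-ratio conversion with 95% confidence bounds
#'
#' @param beta log odds ratio.
#' @param se its standard error.
#' @return named numeric: \code{or} = exp(beta) and the Wald 95% bounds
#'   exp(beta -/+ 1.96 se) (the 0.975 normal quantile).
#' @examples
#' toOrCi(log(1.354), 0.121)  # 1.354 (1.068, 1.716)
#' @export
toOrCi <- function(beta, se) {
  stopifnot(se >= 0)
  z <- stats::qnorm(0.975)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Construct an MREstimate
#'
#' @param method estimator label.
#' @param nSnp number of instruments.
#' @param beta,se estimate and standard error on the log-odds scale.
#' @param pvalue two-sided p-value; computed from the normal reference when
#'   omitted.
#' @param details optional list of method-specific extras.
#' @return an \linkS4class{MREstimate} with the odds-ratio conversion filled
#'   in.
#' @export
MREstimate <- function(method, nSnp, beta, se, pvalue = NULL,
                       details = list()) {
  if (is.null(pvalue))
    pvalue <- if (se > 0) twoSidedNormalP(beta / se) else
      .Machine$double.xmin
  ci <- toOrCi(beta, se)
  new("MREstimate", method = method, nSnp = as.integer(nSnp), beta = beta,
      se = se, pvalue = pvalue, or = ci[["or"]], ciLow = ci[["ci_low"]],
      ciHigh = ci[["ci_high"]], details = details)
}

ratioComponents <- function(h) {
  s <- harmonizedTable(h)
  list(bx = s$bx, by = s$by, sx = s$sx, sy = s$sy,
       theta = s$by / s$bx, w = s$bx^2 / s$sy^2, J = nrow(s))
}

#' Single-SNP Wald ratio
#'
#' beta = by/bx with the first-order standard error sy/|bx|.
#'
#' @param h a \linkS4class{HarmonizedSet} with exactly one instrument (or
#'   the first is used with a warning).
#' @return an \linkS4class{MREstimate} with method "wald".
#' @export
waldRatio <- function(h) {
  s <- harmonizedTable(h)
  if (nrow(s) == 0L) stop("no instruments")
  if (nrow(s) > 1L) warning("waldRatio uses the first of ", nrow(s), " SNPs")
  if (s$bx[1] == 0) stop("degenerate instrument: bx = 0")
  beta <- s$by[1] / s$bx[1]
  se <- s$sy[1] / abs(s$bx[1])
  MREstimate("wald", 1L, beta, se)
}

#' Inverse-variance weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights 1/sy^2 — algebraically the
#' inverse-variance meta-analysis of the per-SNP Wald ratios with
#' first-order weights. The reported standard error is the fixed-effect SE
#' inflated by max(1, sqrt(Q/(J-1))) (multiplicative random effects); the
#' fixed-effect SE and Cochran Q are kept in \code{details}.
#'
#' @param h a \linkS4class{HarmonizedSet}; with a single instrument the
#'   Wald ratio is returned.
#' @return an \linkS4class{MREstimate} with method "ivw".
#' @export
mrIVW <- function(h) {
  r <- ratioComponents(h)
  if (r$J == 0L) stop("no instruments")
  if (r$J == 1L) return(waldRatio(h))
  sw <- sum(r$bx^2 / r$sy^2)
  beta <- sum(r$bx * r$by / r$sy^2) / sw
  seFixed <- sqrt(1 / sw)
  Q <- sum(r$w * (r$theta - beta)^2)
  scale <- max(1, sqrt(Q / (r$J - 1)))
  se <- seFixed * scale
  MREstimate("ivw", r$J, beta, se,
             details = list(seFixed = seFixed, Q = Q, reScale = scale))
}

# weighted regression of by on bx (with intercept), weights 1/sy^2, each SNP
# oriented so bx >= 0; SEs carry multiplicative overdispersion max(1, sigma).
eggerFit <- function(h) {
  r <- ratioComponents(h)
  flip <- r$bx < 0
  bx <- ifelse(flip, -r$bx, r$bx)
  by <- ifelse(flip, -r$by, r$by)
  w <- 1 / r$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  # lm SEs already include sigma; rescale to max(1, sigma)
  seUnscaled <- cf[, "Std. Error"] / sigma
  se <- seUnscaled * max(1, sigma)
  df <- r$J - 2L
  p <- 2 * stats::pt(-abs(cf[, "Estimate"] / se), df)
  list(slope = cf["bx", "Estimate"], slopeSe = se[["bx"]],
       slopeP = max(p[["bx"]], .Machine$double.xmin),
       intercept = cf["(Intercept)", "Estimate"],
       interceptSe = se[["(Intercept)"]],
       interceptP = max(p[["(Intercept)"]], .Machine$double.xmin),
       sigma = sigma, J = r$J)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free intercept
#' (weights 1/sy^2, instruments oriented to non-negative exposure effect).
#' The slope estimates the causal effect under InSIDE; the intercept
#' estimates average directional pleiotropy. P-values use the t reference
#' with J - 2 degrees of freedom and SEs carry multiplicative
#' overdispersion scaling max(1, residual scale).
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @return list with elements \code{slope} and \code{intercept}, both
#'   \linkS4class{MREstimate}s (methods "egger_slope", "egger_intercept").
#' @export
mrEgger <- function(h) {
  r <- ratioComponents(h)
  if (r$J < 3L) stop("MR-Egger needs at least 3 instruments")
  f <- eggerFit(h)
  list(slope = MREstimate("egger_slope", f$J, f$slope, f$slopeSe, f$slopeP,
                          details = list(sigma = f$sigma)),
       intercept = MREstimate("egger_intercept", f$J, f$intercept,
                              f$interceptSe, f$interceptP,
                              details = list(sigma = f$sigma)))
}

weightedMedianPoint <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

bootstrapSe <- function(h, pointFun, nBoot, seed) {
  s <- harmonizedTable(h)
  withSeed(seed, {
    est <- vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(nrow(s), s$bx, s$sx)
      by <- stats::rnorm(nrow(s), s$by, s$sy)
      pointFun(by / bx, bx^2 / s$sy^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' ratios are sorted, weights bx^2/sy^2 normalized, cumulative midpoint
#' weights formed, and the estimate interpolated at the 50% point. The
#' standard error comes from a seeded parametric bootstrap that perturbs
#' the exposure and outcome effects by their SEs. Consistent when valid
#' instruments carry at least half the weight.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an \linkS4class{MREstimate} with method "weighted_median".
#' @export
mrWeightedMedian <- function(h, nBoot = 1000, seed = 1L) {
  r <- ratioComponents(h)
  if (r$J < 3L) stop("weighted median needs at least 3 instruments")
  beta <- weightedMedianPoint(r$theta, r$w)
  se <- bootstrapSe(h, weightedMedianPoint, nBoot, seed)
  MREstimate("weighted_median", r$J, beta, se,
             details = list(nBoot = nBoot, seed = seed))
}

modePoint <- function(theta, w, phi = 1) {
  w <- w / sum(w)
  if (length(unique(theta)) == 1L) return(theta[1])
  spread <- min(stats::sd(theta), stats::mad(theta))
  if (spread == 0) spread <- stats::sd(theta)
  h <- phi * 0.9 * spread * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512L)
  dens <- colSums(w * stats::dnorm(outer(theta, grid, "-") / h) / h)
  mean(grid[dens >= max(dens) - 1e-12 * max(dens)])
}

#' Mode-based estimator (simple or weighted)
#'
#' The argmax of a normal-kernel density over the per-SNP Wald ratios, with
#' uniform weights (simple mode) or normalized inverse-variance weights
#' (weighted mode). Bandwidth is a modified Silverman rule
#' phi * 0.9 * min(sd, MAD) * J^(-1/5); the density is evaluated on a
#' 512-point grid spanning the ratios plus three bandwidths, ties averaged.
#' Consistent when the largest cluster of instruments is valid.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @param weighted use inverse-variance weights (TRUE) or uniform (FALSE).
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an \linkS4class{MREstimate} with method "weighted_mode" or
#'   "simple_mode".
#' @export
mrMode <- function(h, weighted = FALSE, phi = 1, nBoot = 1000, seed = 1L) {
  r <- ratioComponents(h)
  if (r$J < 3L) stop("mode estimator needs at least 3 instruments")
  pf <- if (weighted) function(theta, w) modePoint(theta, w, phi)
        else function(theta, w) modePoint(theta, rep(1, length(theta)), phi)
  beta <- pf(r$theta, r$w)
  se <- bootstrapSe(h, pf, nBoot, seed)
  MREstimate(if (weighted) "weighted_mode" else "simple_mode", r$J, beta, se,
             details = list(phi = phi, nBoot = nBoot, seed = seed))
}

#' All five causal-effect estimators at once
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @param nBoot bootstrap replicates for median/mode SEs.
#' @param seed RNG seed for the bootstraps.
#' @param phi mode bandwidth multiplier.
#' @return named list of \linkS4class{MREstimate}: ivw, egger_slope,
#'   egger_intercept, weighted_median, simple_mode, weighted_mode.
#' @export
mrAllMethods <- function(h, nBoot = 1000, seed = 1L, phi = 1) {
  eg <- mrEgger(h)
  list(ivw = mrIVW(h),
       egger_slope = eg$slope,
       egger_intercept = eg$intercept,
       weighted_median = mrWeightedMedian(h, nBoot, seed),
       simple_mode = mrMode(h, weighted = FALSE, phi, nBoot, seed),
       weighted_mode = mrMode(h, weighted = TRUE, phi, nBoot, seed))
}
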