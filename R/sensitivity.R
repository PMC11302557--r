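#' @include AllClasses.R estimators.R
NULL

#' Cochran's Q heterogeneity test
#'
#' Q = sum w_j (theta_j - theta_hat)^2 over the per-SNP Wald ratios with
#' first-order weights w_j = bx_j^2/sy_j^2, referenced against the
#' fixed-effect IVW estimate (df = J - 1) or, for the Egger reference, the
#' weighted residual sum of squares about the fitted Egger line
#' (df = J - 2). The p-value is the upper chi-square tail.
#'
#' @param h a \linkS4class{HarmonizedSet}.
#' @param reference "ivw" (default, needs J >= 2) or "egger" (J >= 3).
#' @return a \linkS4class{HeterogeneityResult}.
#' @export
cochranQ <- function(h, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  r <- ratioComponents(h)
  if (reference == "ivw") {
    if (r$J < 2L) stop("Cochran Q about IVW needs at least 2 instruments")
    sw <- sum(r$bx^2 / r$sy^2)
    betaFixed <- sum(r$bx * r$by / r$sy^2) / sw
    Q <- sum(r$w * (r$theta - betaFixed)^2)
    df <- r$J - 1L
  } else {
    if (r$J < 3L) stop("Cochran Q about Egger needs at least 3 instruments")
    f <- eggerFit(h)
    bx <- abs(r$bx)
    by <- ifelse(r$bx < 0, -r$by, r$by)
    Q <- sum((by - f$intercept - f$slope * bx)^2 / r$sy^2)
    df <- r$J - 2L
  }
  p <- max(stats::pchisq(Q, df, lower.tail = FALSE), .Machine$double.xmin)
  new("HeterogeneityResult", Q = Q, df = df, pvalue = p)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' A non-zero intercept with p < 0.05 indicates average directional
#' pleiotropy across the instruments.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 instruments.
#' @param alpha significance level for the flag (default 0.05).
#' @return list with \code{intercept} (an \linkS4class{MREstimate}) and
#'   \code{significant} (logical).
#' @export
eggerInterceptTest <- function(h, alpha = 0.05) {
  eg <- mrEgger(h)
  list(intercept = eg$intercept,
       significant = eg$intercept@pvalue < alpha)
}

# leave-one-out fixed-effect IVW slopes for data vectors, vectorized over j
looBetas <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

# weighted squared residuals of each SNP about its leave-one-out slope
pressoResiduals <- function(bx, by, sy) {
  bl <- looBetas(bx, by, sy)
  (by - bl * bx)^2 / sy^2
}

pressoOnce <- function(s, nSim, fixExposure) {
  J <- nrow(s)
  obs <- pressoResiduals(s$bx, s$by, s$sy)
  rssObs <- sum(obs)
  blObs <- looBetas(s$bx, s$by, s$sy)
  # simulate the null: expected outcome effects from the leave-one-out
  # slopes, resampling both sides (or exposure fixed)
  BX <- if (fixExposure) matrix(s$bx, nSim, J, byrow = TRUE) else
    matrix(stats::rnorm(nSim * J, rep(s$bx, each = nSim),
                        rep(s$sx, each = nSim)), nSim, J)
  BY <- matrix(stats::rnorm(nSim * J, rep(blObs * s$bx, each = nSim),
                            rep(s$sy, each = nSim)), nSim, J)
  W <- matrix(rep(1 / s$sy^2, each = nSim), nSim, J)
  SXY <- rowSums(W * BX * BY)
  SXX <- rowSums(W * BX^2)
  BL <- (SXY - W * BX * BY) / (SXX - W * BX^2)
  RES <- W * (BY - BL * BX)^2
  rssSim <- rowSums(RES)
  globalP <- (1 + sum(rssSim >= rssObs)) / (nSim + 1)
  outlierP <- pmin(1, J * (1 + colSums(RES >= rep(obs, each = nSim))) /
                     (nSim + 1))
  names(outlierP) <- s$variant_id
  list(rssObs = rssObs, globalP = globalP, outlierP = outlierP)
}

#' MR-PRESSO global test with iterative outlier removal
#'
#' The observed statistic is the weighted residual sum of squares of each
#' SNP about its leave-one-out IVW slope; its null distribution is built by
#' simulation (outcome effects drawn about the leave-one-out predictions,
#' exposure effects optionally resampled too), and empirical p-values use
#' the add-one rule so they are never exactly zero. Per-SNP outlier
#' p-values come from each SNP's simulated residual distribution,
#' Bonferroni-adjusted by J. While the global test is significant and some
#' adjusted outlier p-value is below \code{significance}, the SNP with the
#' smallest outlier p is removed (one at a time) and everything recomputed;
#' the loop stops when the global test is no longer significant or fewer
#' than 4 instruments would remain. The corrected estimate is IVW on the
#' survivors.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 4 instruments.
#' @param nSim simulated null replicates (default 1000). Note the smallest
#'   attainable Bonferroni-adjusted outlier p is J/(nSim + 1), so nSim must
#'   comfortably exceed J/significance for removal to be possible.
#' @param significance level for the global test and outlier calls
#'   (default 0.05).
#' @param seed RNG seed; the whole procedure is reproducible given it.
#' @param fixExposure treat the exposure effects as fixed in the null
#'   simulation instead of resampling them (default FALSE).
#' @return a \linkS4class{PressoResult}.
#' @export
mrPresso <- function(h, nSim = 1000, significance = 0.05, seed = 1L,
                     fixExposure = FALSE) {
  s <- harmonizedTable(h)
  if (nrow(s) < 4L) stop("MR-PRESSO needs at least 4 instruments")
  nSim <- as.integer(nSim)
  withSeed(seed, {
    first <- pressoOnce(s, nSim, fixExposure)
    cur <- first
    keep <- s
    removed <- character(0)
    while (cur$globalP < significance &&
           any(cur$outlierP < significance) &&
           nrow(keep) > 4L) {
      worst <- names(cur$outlierP)[which.min(cur$outlierP)]
      removed <- c(removed, worst)
      keep <- keep[keep$variant_id != worst, , drop = FALSE]
      cur <- pressoOnce(keep, nSim, fixExposure)
    }
    corrected <- if (length(removed))
      mrIVW(new("HarmonizedSet", snps = keep, exclusions = emptyDropLog()))
      else NULL
    new("PressoResult", globalRSS = first$rssObs, globalP = first$globalP,
        outlierPvalues = cur$outlierP, removedIds = removed,
        correctedEstimate = corrected, nSim = nSim,
        seed = as.integer(seed))
  })
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate with each instrument excluded in turn, plus
#' the all-instrument row, to expose estimates driven by a single SNP.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 2 instruments.
#' @return data.frame with columns \code{excluded} (variant id or "All"),
#'   \code{beta}, \code{se}, \code{pvalue}; J + 1 rows.
#' @export
leaveOneOut <- function(h) {
  s <- harmonizedTable(h)
  J <- nrow(s)
  if (J < 2L) stop("leave-one-out needs at least 2 instruments")
  rows <- lapply(seq_len(J), function(j) {
    est <- mrIVW(subsetHarmonized(h, -j))
    data.frame(excluded = s$variant_id[j], beta = est@beta, se = est@se,
               pvalue = est@pvalue, stringsAsFactors = FALSE)
  })
  all <- mrIVW(h)
  rbind(do.call(rbind, rows),
        data.frame(excluded = "All", beta = all@beta, se = all@se,
                   pvalue = all@pvalue, stringsAsFactors = FALSE))
}
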