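#' @include AllClasses.R instruments.R harmonize.R estimators.R sensitivity.R
NULL

#' Analysis configuration
#'
#' Thresholds and seeds for \code{\link{runPair}}, with the pipeline's
#' defaults: instrument p < 1e-5, MAF >= 0.01, clumping r2 < 0.01 within
#' 10,000 kb, F >= 10, test level 0.05, 1000 bootstrap and simulation
#' replicates.
#'
#' @param pvalThreshold instrument significance cut.
#' @param mafMin minor-allele-frequency floor.
#' @param fMin F-statistic floor.
#' @param r2Max,windowKb LD clumping parameters.
#' @param alpha significance level for tests and summaries.
#' @param nBoot bootstrap replicates for median/mode SEs.
#' @param nSim MR-PRESSO simulation count.
#' @param phi mode bandwidth multiplier.
#' @param seed RNG seed for every stochastic component.
#' @return named list of settings.
#' @export
mrConfig <- function(pvalThreshold = 1e-5, mafMin = 0.01, fMin = 10,
                     r2Max = 0.01, windowKb = 10000, alpha = 0.05,
                     nBoot = 1000, nSim = 1000, phi = 1, seed = 1L) {
  list(pvalThreshold = pvalThreshold, mafMin = mafMin, fMin = fMin,
       r2Max = r2Max, windowKb = windowKb, alpha = alpha, nBoot = nBoot,
       nSim = nSim, phi = phi, seed = as.integer(seed))
}

#' Run the full MR analysis for one exposure/outcome pair
#'
#' Executes instrument selection, harmonization, the five estimators and
#' the sensitivity battery in order. When MR-PRESSO removes outliers, every
#' estimate is recomputed on the survivors and the pre-removal IVW is
#' retained alongside. Fewer than 2 instruments after QC marks the pair
#' "insufficient_instruments" instead of failing.
#'
#' @param exposure,outcome \linkS4class{SummaryStats} objects.
#' @param config settings from \code{\link{mrConfig}}.
#' @param ld optional \linkS4class{LDMatrix} for clumping.
#' @param exposureLabel,outcomeLabel labels carried into reports (e.g.
#'   "genus Bifidobacterium" and "frailty").
#' @return a \linkS4class{PairResult}.
#' @export
runPair <- function(exposure, outcome, config = mrConfig(), ld = NULL,
                    exposureLabel = "exposure", outcomeLabel = "outcome") {
  nInit <- nVariants(exposure)
  sel <- selectInstruments(exposure, ld, config$pvalThreshold, config$mafMin,
                           config$fMin, config$r2Max, config$windowKb)
  h <- harmonize(sel$kept, outcome)
  dropLog <- rbind(sel$dropLog, exclusionLog(h))
  J <- nVariants(h)

  if (J < 2L)
    return(new("PairResult", exposureLabel = exposureLabel,
               outcomeLabel = outcomeLabel,
               status = "insufficient_instruments",
               estimates = list(), estimatesPre = list(),
               sensitivity = list(), nSnpInitial = as.integer(nInit),
               nSnpFinal = as.integer(J), dropLog = dropLog))

  estimateAll <- function(hh) {
    if (nVariants(hh) >= 3L)
      mrAllMethods(hh, config$nBoot, config$seed, config$phi)
    else list(ivw = mrIVW(hh))
  }

  estimates <- estimateAll(h)
  sens <- list(heterogeneity = cochranQ(h, "ivw"))
  if (J >= 3L) {
    sens$heterogeneity_egger <- cochranQ(h, "egger")
    sens$egger_intercept <- eggerInterceptTest(h, config$alpha)
  }
  sens$leave_one_out <- leaveOneOut(h)
  presso <- if (J >= 4L)
    mrPresso(h, config$nSim, config$alpha, config$seed) else NULL
  sens$presso <- presso

  estimatesPre <- list()
  hFinal <- h
  if (!is.null(presso) && length(presso@removedIds)) {
    estimatesPre <- estimates
    hFinal <- subsetHarmonized(h, !variantIds(h) %in% presso@removedIds)
    estimates <- estimateAll(hFinal)
    sens$heterogeneity_corrected <- cochranQ(hFinal, "ivw")
    sens$leave_one_out <- leaveOneOut(hFinal)
  }

  new("PairResult", exposureLabel = exposureLabel,
      outcomeLabel = outcomeLabel, status = "ok", estimates = estimates,
      estimatesPre = estimatesPre, sensitivity = sens,
      nSnpInitial = as.integer(nInit),
      nSnpFinal = as.integer(nVariants(hFinal)), dropLog = dropLog)
}

#' Direction of a causal estimate
#'
#' Positive when the odds ratio exceeds 1, negative when below; an odds
#' ratio of exactly 1 is classified positive by convention (a documented
#' tie rule for a measure-zero case).
#'
#' @param x an \linkS4class{MREstimate}, or a numeric odds ratio.
#' @return "positive" or "negative".
#' @export
classifyDirection <- function(x) {
  or <- if (is(x, "MREstimate")) x@or else as.numeric(x)
  ifelse(or >= 1, "positive", "negative")
}

#' Bonferroni threshold for a taxonomic rank
#'
#' @param n number of taxa tested at the rank.
#' @return 0.05 / n.
#' @export
bonferroniThreshold <- function(n) {
  if (any(n < 1)) stop("n must be >= 1")
  0.05 / n
}

methodLabels <- c(ivw = "Inverse variance weighted",
                  egger_slope = "MR Egger",
                  simple_mode = "Simple mode",
                  weighted_median = "Weighted median",
                  weighted_mode = "Weighted mode")

#' Tidy results table from PairResult objects
#'
#' One row per (pair, method) with numeric columns, the exchange format for
#' \code{\link{summarizeStudy}} and \code{\link{renderTables}}.
#'
#' @param results list of \linkS4class{PairResult}.
#' @param group optional character vector of taxonomic ranks, recycled over
#'   results (stored in the \code{group} column).
#' @return data.frame with columns \code{outcome}, \code{group},
#'   \code{taxon}, \code{nsnp}, \code{method}, \code{se}, \code{or},
#'   \code{ci_low}, \code{ci_high}, \code{pvalue}.
#' @export
resultsTable <- function(results, group = NA_character_) {
  group <- rep_len(group, length(results))
  rows <- mapply(function(pr, grp) {
    ests <- pr@estimates[intersect(names(methodLabels), names(pr@estimates))]
    if (!length(ests)) return(NULL)
    do.call(rbind, lapply(ests, function(e)
      data.frame(outcome = pr@outcomeLabel, group = grp,
                 taxon = pr@exposureLabel, nsnp = e@nSnp,
                 method = methodLabels[[e@method]], se = e@se, or = e@or,
                 ci_low = e@ciLow, ci_high = e@ciHigh, pvalue = e@pvalue,
                 stringsAsFactors = FALSE)))
  }, results, group, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(outcome = character(),
    group = character(), taxon = character(), nsnp = integer(),
    method = character(), se = numeric(), or = numeric(),
    ci_low = numeric(), ci_high = numeric(), pvalue = numeric())
  rownames(out) <- NULL
  out
}

#' Study-level summary of IVW findings
#'
#' Counts, per outcome, the exposures whose inverse-variance weighted
#' p-value is below \code{alpha}, split by direction of the odds ratio, and
#' reports which of them also clear the rank-level Bonferroni threshold
#' 0.05/n.
#'
#' @param results a tidy results data.frame (from \code{\link{resultsTable}}
#'   or \code{\link{readResultTable}}), or a list of
#'   \linkS4class{PairResult}.
#' @param alpha nominal significance level (default 0.05).
#' @param nTaxaPerLevel optional named integer vector giving the number of
#'   taxa tested at each rank (names matching the \code{group} column); by
#'   default the distinct taxa per rank present in \code{results}, which
#'   understates n when only significant rows are supplied.
#' @return a \linkS4class{StudySummary}.
#' @export
summarizeStudy <- function(results, alpha = 0.05, nTaxaPerLevel = NULL) {
  df <- if (is.data.frame(results)) results else resultsTable(results)
  ivw <- df[df$method == methodLabels[["ivw"]], , drop = FALSE]
  sig <- ivw[ivw$pvalue < alpha, , drop = FALSE]
  outcomes <- unique(ivw$outcome)
  counts <- do.call(rbind, lapply(outcomes, function(oc) {
    s <- sig[sig$outcome == oc, , drop = FALSE]
    dir <- classifyDirection(s$or)
    data.frame(outcome = oc, positive = sum(dir == "positive"),
               negative = sum(dir == "negative"), total = nrow(s),
               stringsAsFactors = FALSE)
  }))
  if (is.null(counts))
    counts <- data.frame(outcome = character(), positive = integer(),
                         negative = integer(), total = integer())

  levels <- unique(ivw$group[!is.na(ivw$group)])
  if (is.null(nTaxaPerLevel)) {
    nTaxaPerLevel <- vapply(levels, function(g)
      length(unique(ivw$taxon[ivw$group %in% g])), integer(1))
    names(nTaxaPerLevel) <- levels
  }
  bonf <- data.frame(level = names(nTaxaPerLevel),
                     n = as.integer(nTaxaPerLevel),
                     threshold = bonferroniThreshold(as.integer(nTaxaPerLevel)),
                     stringsAsFactors = FALSE)
  surv <- sig[!is.na(sig$group) & sig$group %in% bonf$level &
              sig$pvalue < bonf$threshold[match(sig$group, bonf$level)], ,
              drop = FALSE]
  new("StudySummary", counts = counts,
      totalSignificant = sum(counts$total), bonferroni = bonf,
      survivors = surv)
}

fmt3 <- function(x) sprintf("%.3f", x)

#' Render results in the publication table layout
#'
#' One row per (pair, method) with columns Group, Bacterial, Nsnp, Methods,
#' SE, "OR (95% CI)" formatted "x.xxx (x.xxx, x.xxx)", and P-value, all
#' rounded to 3 decimals.
#'
#' @param results tidy results data.frame or list of
#'   \linkS4class{PairResult}.
#' @param path optional file path; when given the table is written as TSV.
#' @return the rendered data.frame, invisibly when \code{path} is given.
#' @export
renderTables <- function(results, path = NULL) {
  df <- if (is.data.frame(results)) results else resultsTable(results)
  out <- data.frame(Group = df$group, Bacterial = df$taxon, Nsnp = df$nsnp,
                    Methods = df$method, SE = fmt3(df$se),
                    `OR (95% CI)` = sprintf("%s (%s, %s)", fmt3(df$or),
                                            fmt3(df$ci_low),
                                            fmt3(df$ci_high)),
                    `P-value` = fmt3(df$pvalue),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(out))
  }
  out
}

#' Parse a rendered results table back to tidy form
#'
#' Inverse of \code{\link{renderTables}} up to 3-decimal rounding; also the
#' reader for the bundled published result tables.
#'
#' @param x data.frame in the rendered layout, or a file path to a TSV in
#'   that layout.
#' @param outcome outcome label to attach.
#' @return tidy results data.frame as from \code{\link{resultsTable}}.
#' @export
readResultTable <- function(x, outcome = NA_character_) {
  df <- if (is.character(x))
    utils::read.table(x, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "")
    else x
  cell <- df[["OR (95% CI)"]]
  m <- regmatches(cell, regexec(
    "^\\s*([0-9.]+)\\s*\\(\\s*([0-9.]+)\\s*,\\s*([0-9.]+)\\s*\\)\\s*$", cell))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable OR (95% CI) cell(s): ",
                     paste(utils::head(cell[bad], 3L), collapse = "; "))
  num <- function(i) vapply(m, function(g) as.numeric(g[i]), numeric(1))
  data.frame(outcome = outcome, group = df$Group, taxon = df$Bacterial,
             nsnp = as.integer(df$Nsnp), method = df$Methods,
             se = as.numeric(df$SE), or = num(2), ci_low = num(3),
             ci_high = num(4), pvalue = as.numeric(df[["P-value"]]),
             stringsAsFactors = FALSE)
}

#' Bundled published MR result tables
#'
#' The transcribed two-sample MR result tables relating gut-microbiota
#' exposures to five geriatric-syndrome outcomes (frailty, Parkinson's
#' disease, delirium, insomnia, depression), shipped as plain TSV in the
#' publication layout and parsed to tidy form. A handful of cells are
#' garbled in the published originals and are kept as printed; they do not
#' affect the inverse-variance weighted rows used for counting.
#'
#' @param outcomes which tables to load (default all five).
#' @return tidy results data.frame covering the requested outcomes.
#' @export
bundledResultTables <- function(outcomes = c("frailty", "pd", "delirium",
                                             "insomnia", "depression")) {
  tabs <- lapply(outcomes, function(oc) {
    path <- system.file("extdata", sprintf("mr_results_%s.tsv", oc),
                        package = "mrpipe", mustWork = TRUE)
    readResultTable(path, outcome = oc)
  })
  do.call(rbind, tabs)
}
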