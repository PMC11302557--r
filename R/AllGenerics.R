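#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small generic accessors used throughout the package in place of direct
#' slot access.
#'
#' @param x an object of one of the package's classes.
#' @return \code{variantIds}: character vector of variant identifiers;
#'   \code{nVariants}: integer count; \code{statsTable},
#'   \code{harmonizedTable}: the underlying data.frame;
#'   \code{droppedRecords}, \code{exclusionLog}: the drop/exclusion log
#'   data.frame; \code{ldValues}: the r2 matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))

#' @rdname accessors
#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))

#' @rdname accessors
#' @export
setGeneric("harmonizedTable", function(x) standardGeneric("harmonizedTable"))

#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname accessors
#' @export
setGeneric("ldValues", function(x) standardGeneric("ldValues"))

#' @rdname accessors
#' @export
setMethod("variantIds", "SummaryStats", function(x) x@stats$variant_id)

#' @rdname accessors
#' @export
setMethod("variantIds", "HarmonizedSet", function(x) x@snps$variant_id)

#' @rdname accessors
#' @export
setMethod("variantIds", "LDMatrix", function(x) rownames(x@r2))

#' @rdname accessors
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@stats))

#' @rdname accessors
#' @export
setMethod("nVariants", "HarmonizedSet", function(x) nrow(x@snps))

#' @rdname accessors
#' @export
setMethod("statsTable", "SummaryStats", function(x) x@stats)

#' @rdname accessors
#' @export
setMethod("droppedRecords", "SummaryStats", function(x) x@dropped)

#' @rdname accessors
#' @export
setMethod("harmonizedTable", "HarmonizedSet", function(x) x@snps)

#' @rdname accessors
#' @export
setMethod("exclusionLog", "HarmonizedSet", function(x) x@exclusions)

#' @rdname accessors
#' @export
setMethod("ldValues", "LDMatrix", function(x) x@r2)

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats:", nrow(object@stats), "variants")
  if (nrow(object@dropped)) cat(" (", nrow(object@dropped), " dropped at read)", sep = "")
  cat("\n")
  if (nrow(object@stats)) {
    print(utils::head(object@stats, 3L), row.names = FALSE)
    if (nrow(object@stats) > 3L) cat("...\n")
  }
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix:", nrow(object@r2), "x", ncol(object@r2), "\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", nrow(object@snps), "instruments,",
      nrow(object@exclusions), "excluded\n")
  if (nrow(object@snps)) {
    print(utils::head(object@snps, 3L), row.names = FALSE)
    if (nrow(object@snps) > 3L) cat("...\n")
  }
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] nSnp=%d beta=%.4g se=%.4g p=%.3g OR=%.3f (%.3f, %.3f)\n",
              object@method, object@nSnp, object@beta, object@se,
              object@pvalue, object@or, object@ciLow, object@ciHigh))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran Q = %.4g on %d df, p = %.3g\n",
              object@Q, object@df, object@pvalue))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, global p %.4g (%d sims)\n",
              object@globalRSS, object@globalP, object@nSim))
  if (length(object@removedIds))
    cat("  removed:", paste(object@removedIds, collapse = ", "), "\n")
  else cat("  no outliers removed\n")
})

setMethod("show", "TruthParams", function(object) {
  cat(sprintf("TruthParams: J=%d causalEffect=%.3g invalidFraction=%.2f seed=%d\n",
              object@J, object@causalEffect, object@invalidFraction, object@seed))
})

setMethod("show", "SyntheticPair", function(object) {
  cat("SyntheticPair:", nVariants(object@exposure), "shared variants\n")
})

setMethod("show", "PairResult", function(object) {
  cat(sprintf("PairResult: %s -> %s [%s], %d -> %d SNPs\n",
              object@exposureLabel, object@outcomeLabel, object@status,
              object@nSnpInitial, object@nSnpFinal))
  for (est in object@estimates) show(est)
})

setMethod("show", "StudySummary", function(object) {
  cat("StudySummary:", object@totalSignificant, "IVW-significant pairs\n")
  print(object@counts, row.names = FALSE)
})

#' Component accessors for synthetic pairs and results
#'
#' @param x a \code{SyntheticPair}, \code{PairResult} or \code{StudySummary}.
#' @return \code{exposureStats}/\code{outcomeStats}: the member
#'   \code{SummaryStats}; \code{truthValues}: the realized ground-truth
#'   list; \code{pairEstimates}: named list of \code{MREstimate};
#'   \code{pairSensitivity}: the sensitivity component list;
#'   \code{summaryCounts}: the per-outcome count table.
#' @name component-accessors
NULL

#' @rdname component-accessors
#' @export
setGeneric("exposureStats", function(x) standardGeneric("exposureStats"))

#' @rdname component-accessors
#' @export
setGeneric("outcomeStats", function(x) standardGeneric("outcomeStats"))

#' @rdname component-accessors
#' @export
setGeneric("truthValues", function(x) standardGeneric("truthValues"))

#' @rdname component-accessors
#' @export
setGeneric("pairEstimates", function(x) standardGeneric("pairEstimates"))

#' @rdname component-accessors
#' @export
setGeneric("pairSensitivity", function(x) standardGeneric("pairSensitivity"))

#' @rdname component-accessors
#' @export
setGeneric("summaryCounts", function(x) standardGeneric("summaryCounts"))

#' @rdname component-accessors
#' @export
setMethod("exposureStats", "SyntheticPair", function(x) x@exposure)

#' @rdname component-accessors
#' @export
setMethod("outcomeStats", "SyntheticPair", function(x) x@outcome)

#' @rdname component-accessors
#' @export
setMethod("truthValues", "SyntheticPair", function(x) x@truth)

#' @rdname component-accessors
#' @export
setMethod("pairEstimates", "PairResult", function(x) x@estimates)

#' @rdname component-accessors
#' @export
setMethod("pairSensitivity", "PairResult", function(x) x@sensitivity)

#' @rdname component-accessors
#' @export
setMethod("summaryCounts", "StudySummary", function(x) x@counts)
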