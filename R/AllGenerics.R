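#' @rdname scCounts
#' @export
setGeneric("scCounts", function(x, ...) standardGeneric("scCounts"))

#' @rdname runConditions
#' @export
setGeneric("runConditions", function(x) standardGeneric("runConditions"))

#' @rdname runConditions
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname filterIdentifications
#' @export
setGeneric("filterSummary", function(x) standardGeneric("filterSummary"))

#' @rdname modelSd
#' @export
setGeneric("modelSd", function(fit, mean) standardGeneric("modelSd"))

#' @rdname RefineResult-accessors
#' @export
setGeneric("depReport", function(x) standardGeneric("depReport"))

#' @rdname RefineResult-accessors
#' @export
setGeneric("maiAudit", function(x) standardGeneric("maiAudit"))

#' @rdname RefineResult-accessors
#' @export
setGeneric("plgemFits", function(x) standardGeneric("plgemFits"))

#' @rdname RefineResult-accessors
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))

#' Access the count matrix of a SpectralCounts object
#'
#' @param x a \linkS4class{SpectralCounts} object.
#' @param ... unused.
#' @return the numeric protein-by-run matrix.
#' @rdname scCounts
#' @export
setMethod("scCounts", "SpectralCounts", function(x, ...)
    SummarizedExperiment::assay(x, "counts"))

#' Run-to-condition design accessors
#'
#' \code{runConditions} returns the condition factor aligned with the runs
#' (columns); \code{conditionNames} returns the two condition labels in
#' level order (the first is the default baseline).
#'
#' @param x a \linkS4class{SpectralCounts} object.
#' @rdname runConditions
#' @export
setMethod("runConditions", "SpectralCounts", function(x) {
    cond <- SummarizedExperiment::colData(x)$condition
    if (!is.factor(cond)) cond <- factor(cond, levels = unique(cond))
    cond
})

#' @rdname runConditions
#' @export
setMethod("conditionNames", "SpectralCounts", function(x)
    levels(runConditions(x)))

setMethod("show", "SpectralCounts", function(object) {
    cond <- runConditions(object)
    cat(sprintf("SpectralCounts: %d proteins x %d runs (%s)\n",
        nrow(object), ncol(object),
        paste(sprintf("%s n=%d", levels(cond), tabulate(cond)),
              collapse = " vs ")))
    if (isTRUE(S4Vectors::metadata(object)$normalized))
        cat("  counts normalized to grand-mean run total\n")
    fs <- S4Vectors::metadata(object)$filterSummary
    if (!is.null(fs))
        cat(sprintf("  filtered: %d contaminant, %d decoy removed of %d\n",
                    fs$nContaminant, fs$nDecoy, fs$nInput))
})

setMethod("show", "PlgemFit", function(object) {
    cat("Power-law global error model  ln(s) = k*ln(mean) + c\n")
    cat(sprintf("  k = %.4f, c = %.4f  (R^2 = %.4f, residual SD %.4f)\n",
        object@k, object@c, object@rSquared, object@residualSd))
    cat(sprintf("  fitted on %d points, condition '%s', scope '%s'%s\n",
        object@nPoints, object@condition, object@scope,
        if (object@nBins > 0L) sprintf(", %d rank bins", object@nBins) else ""))
})

setMethod("show", "PipelineConfig", function(object) {
    cat("Two-pass refinement configuration\n")
    cat(sprintf("  first pass p < %g; band [%g, %g]; refined p < %g\n",
        object@pFirst, object@bandLow, object@bandHigh, object@pRefined))
    cat(sprintf("  baseline '%s', null scheme '%s', nIter %d, seed %d\n",
        object@baseline, object@nullScheme, object@nIter, object@seed))
    cat(sprintf("  normalize %s, clamp a-hat %s, second-pass refit %s\n",
        object@normalize, object@clampA, object@refit))
})

setMethod("show", "RefineResult", function(object) {
    counts <- S4Vectors::metadata(object@report)$callCounts
    cat("Two-pass spectral-count refinement result\n")
    cat(sprintf("  %d proteins tested; calls: %d first-pass, %d MAI-refined, %d not significant\n",
        nrow(object@report), counts[["first_pass"]],
        counts[["mai_refined"]], counts[["not_significant"]]))
    cat(sprintf("  pass-1 fit: k = %.4f, c = %.4f (R^2 %.3f); pass-2 fit: k = %.4f, c = %.4f (R^2 %.3f)\n",
        object@fitFirst@k, object@fitFirst@c, object@fitFirst@rSquared,
        object@fitSecond@k, object@fitSecond@c, object@fitSecond@rSquared))
    cat(sprintf("  %d proteins in the refinement band\n",
        nrow(object@stnSecond)))
})

#' Accessors for RefineResult
#'
#' \code{depReport} returns the merged call table, \code{maiAudit} the
#' refinement audit records, \code{plgemFits} both error-model fits, and
#' \code{runSummary} the structured run summary.
#'
#' @param x a \linkS4class{RefineResult}.
#' @name RefineResult-accessors
NULL

#' @rdname RefineResult-accessors
#' @export
setMethod("depReport", "RefineResult", function(x) x@report)

#' @rdname RefineResult-accessors
#' @export
setMethod("maiAudit", "RefineResult", function(x) x@maiAudit)

#' @rdname RefineResult-accessors
#' @export
setMethod("plgemFits", "RefineResult", function(x)
    list(first = x@fitFirst, second = x@fitSecond))

#' @rdname RefineResult-accessors
#' @export
setMethod("runSummary", "RefineResult", function(x) x@summary)
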