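#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData colData<-
NULL

#' SpectralCounts: a protein-by-run spectral count matrix with a two-condition
#' design
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay
#' \code{"counts"} holds non-negative spectral counts (integers when raw,
#' fractional after normalization), rows are proteins (unique accessions as
#' rownames), and \code{colData} carries the \code{run} label and its
#' \code{condition} (exactly two levels, each with at least two replicate
#' runs). Optional \code{rowData} columns \code{description},
#' \code{isContaminant} and \code{isDecoy} drive identification filtering.
#'
#' @seealso [SpectralCounts()], [readSpectralCounts()]
#' @export
setClass("SpectralCounts", contains = "SummarizedExperiment")

setValidity("SpectralCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(cnt))
            msg <- c(msg, "counts must not contain missing values")
        else if (any(cnt < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    ids <- rownames(object)
    if (is.null(ids) || any(!nzchar(ids)))
        msg <- c(msg, "all proteins need non-empty identifiers (rownames)")
    else if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicated protein identifiers: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'condition' column")
    else {
        tab <- table(cd$condition)
        if (length(tab) != 2L)
            msg <- c(msg, sprintf("exactly two conditions required, found %d",
                                  length(tab)))
        if (any(tab < 2L))
            msg <- c(msg, "every condition needs at least two replicate runs")
    }
    if (length(msg)) msg else TRUE
})

#' Fitted power-law global error model
#'
#' Holds the ordinary least-squares fit of \eqn{\ln s = k \ln \bar{x} + c +
#' \epsilon} over proteins of one condition, where \eqn{\bar{x}} and \eqn{s}
#' are the replicate mean and sample standard deviation of spectral counts.
#' The model-expected standard deviation at mean \eqn{m} is
#' \eqn{e^{c} m^{k}} (see [modelSd()]).
#'
#' @slot k slope of the log-log regression (dimensionless).
#' @slot c intercept, in log-SD units (natural logarithms throughout).
#' @slot rSquared coefficient of determination of the fit.
#' @slot residualSd standard deviation of the regression residuals
#'   (the \eqn{\epsilon} term).
#' @slot nPoints number of (protein or binned) points used in the fit.
#' @slot condition condition label the model was fitted on (or "pooled").
#' @slot scope "condition" (one condition's replicates) or "pooled"
#'   (per-condition points from both conditions stacked).
#' @slot nBins number of rank bins (0 = unbinned, protein-level fit).
#' @export
setClass("PlgemFit",
    representation(k = "numeric", c = "numeric", rSquared = "numeric",
                   residualSd = "numeric", nPoints = "integer",
                   condition = "character", scope = "character",
                   nBins = "integer"))

setValidity("PlgemFit", function(object) {
    msg <- character()
    if (object@nPoints < 3L)
        msg <- c(msg, "a power-law fit needs at least 3 points")
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Per-protein signal-to-noise test results
#'
#' A \linkS4class{DataFrame} subclass with one row per tested protein and
#' columns \code{proteinId}, \code{meanA}, \code{meanB} (replicate means per
#' condition), \code{sdModelA}, \code{sdModelB} (model SD at those means),
#' \code{stn} (signed statistic) and \code{pValue} (empirical two-sided tail
#' fraction against the pooled resampling null), plus \code{passLabel}
#' identifying the pipeline pass. Metadata records the conditions compared
#' and the null-pool provenance.
#'
#' @export
setClass("StnResults", contains = "DFrame")

#' Merged differential-expression report
#'
#' A \linkS4class{DataFrame} subclass with one row per protein:
#' \code{proteinId}, condition means from the deciding pass, \code{log2fc},
#' \code{pFirst}, \code{pRefined} (NA for proteins never re-tested) and
#' \code{call}, one of \code{"first_pass"}, \code{"mai_refined"},
#' \code{"not_significant"} (the two significant call sets are disjoint by
#' construction). Metadata stores the call counts and thresholds.
#'
#' @export
setClass("DepReport", contains = "DFrame")

#' Pipeline configuration
#'
#' @slot pFirst first-pass significance threshold (strict; default 0.01).
#' @slot bandLow,bandHigh inclusive bounds of the refinement band
#'   (defaults 0.01, 0.05).
#' @slot pRefined post-refinement significance threshold (default 0.03).
#' @slot baseline condition label used for model fitting and as the `A' side
#'   of the statistic; NA means the first condition level.
#' @slot nIter resampling iterations for the null pool; when the exhaustive
#'   enumeration of splits is no larger than this, enumeration is used and
#'   the pipeline is fully deterministic.
#' @slot seed master seed; all randomness in a run derives from it.
#' @slot normalize scale each run to the grand-mean run total first.
#' @slot clampA clamp the MAI shrinkage coefficient to at most 1.
#' @slot refit refit the error model on the refined matrix for the second
#'   pass (FALSE reuses the first-pass fit).
#' @slot nullScheme "permutation" (split all runs into pseudo-groups of the
#'   real group sizes) or "baseline-split" (split the baseline replicates
#'   into two non-empty pseudo-groups).
#' @export
setClass("PipelineConfig",
    representation(pFirst = "numeric", bandLow = "numeric",
                   bandHigh = "numeric", pRefined = "numeric",
                   baseline = "character", nIter = "integer",
                   seed = "integer", normalize = "logical",
                   clampA = "logical", refit = "logical",
                   nullScheme = "character"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (!(object@pFirst > 0 && object@pFirst <= object@bandLow &&
          object@bandLow <= object@bandHigh && object@bandHigh < 1))
        msg <- c(msg, "need 0 < pFirst <= bandLow <= bandHigh < 1")
    if (!(object@pRefined > 0 && object@pRefined < 1))
        msg <- c(msg, "need 0 < pRefined < 1")
    if (object@nIter < 1L)
        msg <- c(msg, "nIter must be >= 1")
    if (!object@nullScheme %in% c("permutation", "baseline-split"))
        msg <- c(msg, "nullScheme must be 'permutation' or 'baseline-split'")
    if (length(msg)) msg else TRUE
})

#' Result of the two-pass refinement pipeline
#'
#' @slot counts the (optionally normalized) matrix tested in the first pass.
#' @slot refined the matrix with band proteins' counts replaced by their
#'   moment-adjusted values (identical to \code{counts} outside the band).
#' @slot fitFirst,fitSecond power-law error-model fits of the two passes.
#' @slot stnFirst first-pass test results for every protein.
#' @slot stnSecond re-test results for band proteins only.
#' @slot maiAudit per-protein, per-condition refinement audit records.
#' @slot report merged differential-expression report.
#' @slot config the configuration used.
#' @slot summary run summary list: seeds, fit parameters, stratified p-value
#'   summaries, before/after log-log regression on the significant set, and
#'   call counts.
#' @export
setClass("RefineResult",
    representation(counts = "SpectralCounts", refined = "SpectralCounts",
                   fitFirst = "PlgemFit", fitSecond = "PlgemFit",
                   stnFirst = "StnResults", stnSecond = "StnResults",
                   maiAudit = "DFrame", report = "DepReport",
                   config = "PipelineConfig", summary = "list"))
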