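#' Model-based signal-to-noise statistic
#'
#' \eqn{STN = (\bar{x}_A - \bar{x}_B) / (\sigma_A + \sigma_B)} with
#' model-expected (not sample) standard deviations in the denominator.
#' Antisymmetric in the two conditions.
#'
#' @param meanA,meanB non-negative condition means (vectorized).
#' @param sdA,sdB positive model SDs at those means; \code{sdA + sdB} must
#'   be positive.
#' @return signed numeric statistic(s).
#' @examples
#' stnStatistic(10, 5, 2, 1.5)   # 5 / 3.5
#' @export
stnStatistic <- function(meanA, meanB, sdA, sdB) {
    if (any(sdA + sdB <= 0))
        stop("sum of model SDs must be positive")
    (meanA - meanB) / (sdA + sdB)
}

# internal: pooled null STNs for a list of splits; each split is a list
# with integer column indices $a and $b
.nullFromSplits <- function(cnt, fit, splits) {
    out <- vector("list", length(splits))
    for (i in seq_along(splits)) {
        ma <- rowMeans(cnt[, splits[[i]]$a, drop = FALSE])
        mb <- rowMeans(cnt[, splits[[i]]$b, drop = FALSE])
        out[[i]] <- unname(stnStatistic(ma, mb, .modelSdFloored(fit, ma),
                                        .modelSdFloored(fit, mb)))
    }
    unlist(out, use.names = FALSE)
}

# all ordered splits of 'cols' into two non-empty groups
.enumerateBipartitions <- function(cols) {
    n <- length(cols)
    sets <- unlist(lapply(seq_len(n - 1L),
        function(s) utils::combn(n, s, simplify = FALSE)), recursive = FALSE)
    lapply(sets, function(idx) list(a = cols[idx], b = cols[-idx]))
}

# all splits of 'cols' into an A-group of size nA (complement is B)
.enumerateSizedSplits <- function(cols, nA) {
    sets <- utils::combn(length(cols), nA, simplify = FALSE)
    lapply(sets, function(idx) list(a = cols[idx], b = cols[-idx]))
}

#' Build the pooled null distribution of the signal-to-noise statistic
#'
#' Recomputes the per-protein statistic under splits of replicate runs into
#' two pseudo-conditions carrying no real condition contrast, and pools the
#' values across proteins and splits. Two schemes are available:
#' \describe{
#'   \item{\code{"permutation"} (default)}{splits all runs of both
#'   conditions into pseudo-groups of the real group sizes (for triplicates,
#'   the 20 ordered 3-vs-3 splits). The pseudo-group means then have the
#'   same sampling variance as the observed contrast, which is what makes
#'   the resulting p-values uniform under the null.}
#'   \item{\code{"baseline-split"}}{splits only the baseline condition's
#'   replicates into two non-empty pseudo-groups (for triplicates, 6 ordered
#'   1-vs-2 splits). Never contaminated by a real effect, but the unbalanced
#'   pseudo-groups make the pool wider than the observed statistic and the
#'   test conservative; retained for sensitivity analysis.}
#' }
#' When the exhaustive enumeration has at most \code{nIter} splits (or
#' \code{exhaustive = TRUE}) every split is used exactly once and the pool
#' is deterministic; otherwise \code{nIter} splits are drawn with the given
#' seed.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param fit a \linkS4class{PlgemFit} providing the model SDs.
#' @param baseline baseline condition label (default: first level); used by
#'   the \code{"baseline-split"} scheme.
#' @param nIter maximum number of splits drawn in Monte-Carlo mode.
#' @param seed RNG seed for Monte-Carlo mode (required there; unused when
#'   exhaustive).
#' @param scheme null-generation scheme, see Details.
#' @param exhaustive force (TRUE) or forbid (FALSE) exhaustive enumeration;
#'   default \code{NA} enumerates exactly when feasible within \code{nIter}.
#' @return numeric vector of pooled null statistics, with attributes
#'   \code{scheme}, \code{exhaustive} and \code{nSplits}.
#' @export
nullStnDistribution <- function(x, fit, baseline = NULL, nIter = 2000L,
                                seed = NULL,
                                scheme = c("permutation", "baseline-split"),
                                exhaustive = NA) {
    scheme <- match.arg(scheme)
    nIter <- as.integer(nIter)
    if (nIter < 1L) stop("nIter must be >= 1")
    baseline <- resolveBaseline(x, baseline %||% NA_character_)
    cnt <- scCounts(x)
    if (scheme == "baseline-split") {
        cols <- conditionColumns(x, baseline)
        if (length(cols) < 3L)
            stop("baseline-split needs at least 3 baseline replicates")
        total <- 2L^length(cols) - 2L
        enum <- function() .enumerateBipartitions(cols)
        draw <- function() {
            repeat {
                pick <- which(stats::runif(length(cols)) < 0.5)
                if (length(pick) > 0L && length(pick) < length(cols))
                    return(list(a = cols[pick], b = cols[-pick]))
            }
        }
    } else {
        cond <- runConditions(x)
        nA <- sum(cond == levels(cond)[1L])
        cols <- seq_len(ncol(cnt))
        total <- choose(length(cols), nA)
        enum <- function() .enumerateSizedSplits(cols, nA)
        draw <- function() {
            idx <- sample(length(cols), nA)
            list(a = cols[idx], b = cols[-idx])
        }
    }
    useExhaustive <- if (is.na(exhaustive)) total <= nIter else
        isTRUE(exhaustive)
    if (useExhaustive && total > 1e5)
        stop(sprintf("exhaustive enumeration of %d splits is not practical",
                     total))
    splits <- if (useExhaustive) enum() else {
        if (is.null(seed))
            stop("Monte-Carlo null generation requires a seed")
        withSeed(seed, replicate(nIter, draw(), simplify = FALSE))
    }
    pool <- .nullFromSplits(cnt, fit, splits)
    structure(pool, scheme = scheme, exhaustive = useExhaustive,
              nSplits = length(splits))
}

#' Per-protein signal-to-noise tests against a pooled null
#'
#' Computes the observed statistic for every protein (condition means over
#' all replicates, model SDs at those means, with a half-count floor for
#' zero means) and the raw empirical two-sided p-value
#' \eqn{p = \#\{|null| \ge |stn|\} / |null|}. Zero is attainable; no
#' continuity correction is applied because proteins more extreme than every
#' null value are genuinely off the resampling scale (a pseudo-count
#' variant is available via \code{pseudocount = TRUE}, giving
#' \eqn{(r+1)/(N+1)}).
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param fit a \linkS4class{PlgemFit}.
#' @param nullPool numeric null sample from [nullStnDistribution()].
#' @param passLabel label recorded in the results (e.g. \code{"first_pass"}).
#' @param pseudocount use the (r+1)/(N+1) tail estimator instead of the raw
#'   fraction.
#' @return a \linkS4class{StnResults} with one row per protein, in row
#'   order of \code{x}.
#' @export
stnPvalues <- function(x, fit, nullPool, passLabel = "first_pass",
                       pseudocount = FALSE) {
    if (!length(nullPool)) stop("empty null pool")
    conds <- conditionNames(x)
    cnt <- scCounts(x)
    mA <- rowMeans(cnt[, conditionColumns(x, conds[1L]), drop = FALSE])
    mB <- rowMeans(cnt[, conditionColumns(x, conds[2L]), drop = FALSE])
    sdA <- .modelSdFloored(fit, mA)
    sdB <- .modelSdFloored(fit, mB)
    stn <- stnStatistic(mA, mB, sdA, sdB)
    sortedNull <- sort(abs(nullPool))
    n <- length(sortedNull)
    greaterEq <- n - findInterval(abs(stn), sortedNull, left.open = TRUE)
    p <- if (pseudocount) (greaterEq + 1) / (n + 1) else greaterEq / n
    res <- S4Vectors::DataFrame(
        proteinId = rownames(x), meanA = unname(mA), meanB = unname(mB),
        sdModelA = unname(sdA), sdModelB = unname(sdB),
        stn = unname(stn), pValue = unname(p),
        passLabel = passLabel, row.names = rownames(x))
    res <- new("StnResults", res)
    S4Vectors::metadata(res) <- list(conditions = conds,
        nullSize = n, nullScheme = attr(nullPool, "scheme"),
        nullExhaustive = attr(nullPool, "exhaustive"))
    res
}

#' Mean p-value by abundance stratum
#'
#' Splits proteins at a mean-count threshold (default 5, the conventional
#' low-abundance boundary for spectral counts) and reports the count and
#' mean p-value per stratum. Empty strata are omitted rather than reported
#' as errors.
#'
#' @param results a \linkS4class{StnResults}.
#' @param x the \linkS4class{SpectralCounts} the results came from.
#' @param thresholdMean stratum boundary on the mean count.
#' @param condition condition whose replicate mean stratifies the proteins;
#'   \code{NULL} (default) uses the mean over all runs.
#' @return data.frame with columns \code{stratum}, \code{n}, \code{meanP}.
#' @export
stratifiedPvalues <- function(results, x, thresholdMean = 5,
                              condition = NULL) {
    if (!all(results$proteinId %in% rownames(x)))
        stop("results and matrix are not aligned")
    cnt <- scCounts(x)[results$proteinId, , drop = FALSE]
    if (!is.null(condition))
        cnt <- cnt[, conditionColumns(x, condition), drop = FALSE]
    m <- rowMeans(cnt)
    strata <- ifelse(m < thresholdMean,
                     sprintf("mean < %g", thresholdMean),
                     sprintf("mean >= %g", thresholdMean))
    agg <- lapply(split(results$pValue, strata), function(p)
        c(n = length(p), meanP = mean(p)))
    out <- data.frame(stratum = names(agg),
                      n = as.integer(vapply(agg, `[[`, 0, "n")),
                      meanP = vapply(agg, `[[`, 0, "meanP"),
                      row.names = NULL)
    out[order(out$stratum), ]
}
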