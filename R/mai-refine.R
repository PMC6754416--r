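#' Population third-moment skewness
#'
#' \eqn{g_1 = m_3 / m_2^{3/2}} with n-denominator central moments. Returns
#' 0 for a zero-variance vector. With triplicates only the sign matters for
#' adjustment targeting; values within 1e-12 of zero are treated as exactly
#' symmetric ("truly estimated") by [maiAdjust()].
#'
#' @param values numeric vector of at least 3 replicate measurements.
#' @return the skewness \eqn{g_1}.
#' @examples
#' momentSkewness(c(1, 2, 9))   # 30 / (38/3)^1.5
#' @export
momentSkewness <- function(values) {
    if (length(values) < 3L) stop("skewness needs at least 3 values")
    d <- values - mean(values)
    m2 <- mean(d^2)
    if (m2 == 0) return(0)
    mean(d^3) / m2^1.5
}

#' MAI shrinkage coefficient
#'
#' \eqn{\hat{a} = (\hat{\sigma}_x^2 / \hat{\sigma}_w^2)^{1/2}}: the ratio of
#' the model-expected (error-free) SD to the measured n-denominator SD.
#' By default the coefficient is clamped to at most 1, because a ratio above
#' 1 would move the adjusted extreme \emph{away} from the replicate mean --
#' the opposite of the variance reduction the adjustment exists for. The
#' unclamped ratio is preserved in the audit records.
#'
#' @param sigmaX positive model SD at the replicate mean.
#' @param sigmaW measured n-denominator SD; must be positive (a zero SD
#'   means no adjustment is possible).
#' @param clamp clamp the ratio to [0, 1] (default TRUE).
#' @return the shrinkage coefficient.
#' @export
shrinkageCoefficient <- function(sigmaX, sigmaW, clamp = TRUE) {
    if (sigmaW <= 0)
        stop("sigmaW must be positive: zero measured SD admits no adjustment")
    a <- sigmaX / sigmaW
    if (clamp) min(1, a) else a
}

#' Moment-adjusted imputation of one replicate vector
#'
#' Skewness-directed refinement: when the replicates are right-skewed the
#' largest observation is regarded as overestimated and replaced by
#' \eqn{W_{(n)}\hat{a} + \bar{W}(1 - \hat{a})}; when left-skewed the
#' smallest observation is replaced by the analogous convex combination;
#' a symmetric vector (|skewness| <= 1e-12) or one with zero measured SD is
#' returned unchanged. All other positions are untouched, so the refined
#' vector differs from the input in at most one position.
#'
#' @param values numeric vector of n >= 3 replicate counts (any order; the
#'   extreme order statistic is located internally).
#' @param sigmaX positive model SD at the replicate mean (the error-free
#'   \eqn{\hat{\sigma}_x}).
#' @param clamp clamp \eqn{\hat{a}} to at most 1 (see
#'   [shrinkageCoefficient()]).
#' @return list with \code{refined} (numeric, same order as input) and
#'   \code{record}, a one-row data.frame audit with the mean, SDs, raw and
#'   used \eqn{\hat{a}}, skewness, which order statistic was replaced
#'   (\code{"largest"}, \code{"smallest"} or \code{"none"}), and an
#'   \code{orderViolated} flag set when the adjusted extreme crossed its
#'   neighbouring order statistic (possible under strong shrinkage, since
#'   the replicate mean need not lie between the two extremes).
#' @examples
#' maiAdjust(c(1, 2, 9), sigmaX = 0.5 * sqrt(38 / 3))$refined  # 1 2 6.5
#' @export
maiAdjust <- function(values, sigmaX, clamp = TRUE) {
    if (length(values) < 3L) stop("need at least 3 replicate values")
    if (sigmaX <= 0) stop("sigmaX must be positive")
    wBar <- mean(values)
    sigmaW <- sdPop(values)
    skew <- momentSkewness(values)
    record <- data.frame(
        wBar = wBar, sigmaW = sigmaW, sigmaX = sigmaX, skewness = skew,
        aHatRaw = if (sigmaW > 0) sigmaX / sigmaW else NA_real_,
        aHatUsed = NA_real_, adjustedIndex = "none",
        orderViolated = FALSE, stringsAsFactors = FALSE)
    refined <- values
    if (sigmaW > 0 && abs(skew) > 1e-12) {
        a <- shrinkageCoefficient(sigmaX, sigmaW, clamp = clamp)
        pos <- if (skew > 0) which.max(values) else which.min(values)
        refined[pos] <- values[pos] * a + wBar * (1 - a)
        record$aHatUsed <- a
        record$adjustedIndex <- if (skew > 0) "largest" else "smallest"
        # strong shrinkage can carry the extreme past its neighbouring
        # order statistic (the mean need not lie between them); flag it
        record$orderViolated <- if (skew > 0)
            refined[pos] < max(values[-pos])
        else refined[pos] > min(values[-pos])
    }
    list(refined = refined, record = record)
}

#' Refine one protein's replicate counts in both conditions
#'
#' Applies [maiAdjust()] independently to each condition's replicates, with
#' \eqn{\hat{\sigma}_x} evaluated by the error model at that condition's
#' replicate mean. A condition with zero mean admits no model SD and is
#' recorded as unadjusted.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param fit a \linkS4class{PlgemFit}.
#' @param proteinId one protein accession present in \code{x}.
#' @param clamp clamp \eqn{\hat{a}} to at most 1.
#' @return \linkS4class{DataFrame} with one row per condition:
#'   \code{proteinId}, \code{condition}, the measured values \code{w}
#'   (NumericList), the audit fields of [maiAdjust()], the \code{refined}
#'   values (NumericList), and a \code{note} for skipped conditions.
#' @export
refineProtein <- function(x, fit, proteinId, clamp = TRUE) {
    if (!proteinId %in% rownames(x))
        stop(sprintf("protein '%s' not found", proteinId))
    rows <- lapply(conditionNames(x), function(cc) {
        w <- scCounts(x)[proteinId, conditionColumns(x, cc)]
        .refineOneCondition(w, fit, proteinId, cc, clamp)
    })
    do.call(rbind, rows)
}

# one (protein, condition) refinement record
.refineOneCondition <- function(w, fit, proteinId, condition, clamp) {
    if (mean(w) <= 0) {
        rec <- data.frame(wBar = mean(w), sigmaW = sdPop(w),
            sigmaX = NA_real_, skewness = momentSkewness(w),
            aHatRaw = NA_real_, aHatUsed = NA_real_,
            adjustedIndex = "none", orderViolated = FALSE,
            stringsAsFactors = FALSE)
        refined <- w
        note <- "zero condition mean: no model SD, no adjustment"
    } else {
        adj <- maiAdjust(w, sigmaX = modelSd(fit, mean(w)), clamp = clamp)
        rec <- adj$record
        refined <- adj$refined
        note <- ""
    }
    out <- S4Vectors::DataFrame(proteinId = proteinId,
                                condition = condition,
                                w = IRanges::NumericList(unname(w)))
    for (f in names(rec)) out[[f]] <- rec[[f]]
    out$refined <- IRanges::NumericList(unname(refined))
    out$note <- note
    out
}

#' Refine a set of proteins, returning the refined matrix and audit table
#'
#' Batch version of [refineProtein()]: the returned matrix equals \code{x}
#' except that the listed proteins' counts are replaced by their
#' moment-adjusted values (at most one replicate changed per condition).
#'
#' @inheritParams refineProtein
#' @param proteinIds accessions of the proteins to refine (typically the
#'   first-pass borderline band).
#' @return list with \code{counts} (the refined
#'   \linkS4class{SpectralCounts}) and \code{audit} (row-bound
#'   [refineProtein()] records; zero-row when \code{proteinIds} is empty).
#' @export
refineProteins <- function(x, fit, proteinIds, clamp = TRUE) {
    missing <- setdiff(proteinIds, rownames(x))
    if (length(missing))
        stop(sprintf("unknown protein(s): %s",
                     paste(utils::head(missing, 3L), collapse = ", ")))
    cnt <- scCounts(x)
    audits <- vector("list", length(proteinIds))
    condCols <- lapply(conditionNames(x), function(cc)
        conditionColumns(x, cc))
    for (i in seq_along(proteinIds)) {
        pid <- proteinIds[i]
        recs <- lapply(seq_along(condCols), function(j) {
            w <- cnt[pid, condCols[[j]]]
            rec <- .refineOneCondition(w, fit, pid,
                                       conditionNames(x)[j], clamp)
            cnt[pid, condCols[[j]]] <<- unlist(rec$refined)
            rec
        })
        audits[[i]] <- do.call(rbind, recs)
    }
    audit <- if (length(audits)) do.call(rbind, audits) else
        .refineOneCondition(c(0, 0, 0), NULL, "x", "x", clamp)[0, ]
    out <- x
    SummarizedExperiment::assay(out, "counts") <- cnt
    list(counts = out, audit = audit)
}
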