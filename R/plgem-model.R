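# internal: per-protein replicate mean and sample SD for one condition
.conditionStats <- function(x, condition) {
    cols <- conditionColumns(x, condition)
    cnt <- scCounts(x)[, cols, drop = FALSE]
    list(mean = rowMeans(cnt), sd = apply(cnt, 1L, stats::sd))
}

# internal: OLS of ln(sd) on ln(mean), optionally through rank-binned
# averages of the points (parity with the classic PLGEM modelling points)
.loglogOls <- function(m, s, nBins = 0L) {
    ok <- m > 0 & s > 0
    x <- log(m[ok]); y <- log(s[ok])
    if (length(x) < 3L)
        stop(sprintf("need at least 3 proteins with positive mean and SD, have %d",
                     length(x)))
    if (nBins > 0L) {
        o <- order(x)
        grp <- cut(seq_along(o), breaks = nBins, labels = FALSE)
        x <- as.numeric(tapply(x[o], grp, mean))
        y <- as.numeric(tapply(y[o], grp, mean))
        if (length(x) < 3L) stop("too few rank bins for a fit")
    }
    fit <- stats::lm.fit(cbind(1, x), y)
    res <- fit$residuals
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    list(intercept = unname(fit$coefficients[1L]),
         slope = unname(fit$coefficients[2L]),
         rSquared = r2, residualSd = stats::sd(res), n = length(x))
}

#' Fit the power-law global error model
#'
#' Ordinary least squares of \eqn{\ln(s)} on \eqn{\ln(\bar{x})} over
#' proteins of the designated condition, where \eqn{\bar{x}} is the
#' replicate mean and \eqn{s} the sample (n-1 denominator) standard
#' deviation. Proteins with zero mean or zero SD carry no information about
#' the log-log relation and are excluded from fitting (they still receive a
#' model SD downstream). Natural logarithms throughout.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param condition condition whose replicates are fitted; default is the
#'   first condition level (the baseline).
#' @param scope \code{"condition"} fits the designated condition's points;
#'   \code{"pooled"} stacks per-condition (mean, SD) points from both
#'   conditions.
#' @param nBins if positive, the fit runs through this many rank-binned
#'   average points instead of raw protein points (classic-PLGEM parity
#'   mode); the default 0 is the plain protein-level regression.
#' @return a \linkS4class{PlgemFit}.
#' @examples
#' sim <- simulateCounts(200, seed = 7)
#' fitPlgem(sim$counts)
#' @export
fitPlgem <- function(x, condition = NULL, scope = c("condition", "pooled"),
                     nBins = 0L) {
    scope <- match.arg(scope)
    condition <- resolveBaseline(x, condition %||% NA_character_)
    if (scope == "condition") {
        st <- .conditionStats(x, condition)
        m <- st$mean; s <- st$sd
    } else {
        sts <- lapply(conditionNames(x), function(cc) .conditionStats(x, cc))
        m <- unlist(lapply(sts, `[[`, "mean"), use.names = FALSE)
        s <- unlist(lapply(sts, `[[`, "sd"), use.names = FALSE)
    }
    ols <- .loglogOls(m, s, nBins = as.integer(nBins))
    new("PlgemFit", k = ols$slope, c = ols$intercept,
        rSquared = ols$rSquared, residualSd = ols$residualSd,
        nPoints = as.integer(ols$n),
        condition = if (scope == "pooled") "pooled" else condition,
        scope = scope, nBins = as.integer(nBins))
}

#' Model-expected standard deviation at a given mean
#'
#' Evaluates \eqn{\hat{\sigma}(m) = e^{c} m^{k}} from a fitted power-law
#' error model. This is the sigma-expected of the variance diagnostics and
#' the error-free \eqn{\hat{\sigma}_x} of the MAI shrinkage coefficient.
#'
#' @param fit a \linkS4class{PlgemFit}.
#' @param mean strictly positive mean value(s).
#' @return positive numeric of the same length as \code{mean}.
#' @rdname modelSd
#' @export
setMethod("modelSd", "PlgemFit", function(fit, mean) {
    if (any(mean <= 0)) stop("modelSd is defined for positive means only")
    exp(fit@c) * mean^fit@k
})

# internal: model SD with a half-count floor so that zero pseudo-group
# means (protein absent from a set of runs) still get a usable positive SD
# in the signal-to-noise denominator
.modelSdFloored <- function(fit, mean, floorMean = 0.5)
    exp(fit@c) * pmax(mean, floorMean)^fit@k

#' Per-protein variance diagnostics
#'
#' Compares the measured replicate SD with the model-expected SD at each
#' protein's mean, for proteins with positive mean in the chosen condition.
#' A ratio (expected / measured) below 1 marks a protein noisier than the
#' global error model predicts -- the signature of data-dependent
#' acquisition undersampling at low abundance.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param fit a \linkS4class{PlgemFit} for the same data.
#' @param condition condition to diagnose; default = the fit's condition
#'   (the baseline when the fit is pooled).
#' @return \linkS4class{DataFrame} with \code{proteinId}, \code{scMean},
#'   \code{sigmaMeasured}, \code{sigmaExpected} and \code{ratio}
#'   (\code{NA} when the measured SD is zero).
#' @export
varianceDiagnostics <- function(x, fit, condition = NULL) {
    condition <- resolveBaseline(x, condition %||%
        (if (fit@condition %in% conditionNames(x)) fit@condition
         else NA_character_))
    st <- .conditionStats(x, condition)
    keep <- st$mean > 0
    sigmaExp <- modelSd(fit, st$mean[keep])
    measured <- st$sd[keep]
    S4Vectors::DataFrame(
        proteinId = rownames(x)[keep],
        scMean = unname(st$mean[keep]),
        sigmaMeasured = unname(measured),
        sigmaExpected = unname(sigmaExp),
        ratio = unname(ifelse(measured > 0, sigmaExp / measured, NA_real_)))
}

#' Log-log SD-versus-mean regression over a protein subset
#'
#' The before/after-refinement diagnostic: ordinary least squares of
#' \eqn{\ln(SD)} on \eqn{\ln(mean)} over a chosen set of proteins
#' (typically the differential proteins), on whichever matrix is supplied.
#' With \code{proteins = NULL} and the same condition this reproduces the
#' [fitPlgem()] regression.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param proteins protein identifiers to include (default all).
#' @param condition condition whose replicates are summarized (default the
#'   baseline).
#' @return list with \code{slope}, \code{intercept}, \code{rSquared} and
#'   \code{n} (points used).
#' @export
loglogRegression <- function(x, proteins = NULL, condition = NULL) {
    condition <- resolveBaseline(x, condition %||% NA_character_)
    if (!is.null(proteins)) {
        missing <- setdiff(proteins, rownames(x))
        if (length(missing))
            stop(sprintf("unknown protein(s): %s",
                         paste(utils::head(missing, 3L), collapse = ", ")))
        x <- x[rownames(x) %in% proteins, ]
    }
    st <- .conditionStats(x, condition)
    ols <- .loglogOls(st$mean, st$sd)
    list(slope = ols$slope, intercept = ols$intercept,
         rSquared = ols$rSquared, n = ols$n)
}
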