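#' Build a pipeline configuration
#'
#' Thresholds follow the two-pass calling scheme: confident calls at
#' \code{pValue < pFirst} in the first pass; proteins with first-pass
#' p-value inside the inclusive band \code{[bandLow, bandHigh]} are refined
#' by moment-adjusted imputation and re-tested at \code{pValue < pRefined}.
#' Note the asymmetry at the lower bound: a protein with p exactly equal to
#' \code{pFirst} is not a first-pass call (strict inequality) but does enter
#' the band (inclusive bound).
#'
#' @param pFirst,bandLow,bandHigh,pRefined calling thresholds (defaults
#'   0.01, 0.01, 0.05, 0.03).
#' @param baseline condition used for error-model fitting; NA = first level.
#' @param nIter resampling iterations (exhaustive enumeration is used
#'   instead whenever it needs no more splits than this).
#' @param seed master seed for all randomness in the run.
#' @param normalize scale runs to the grand-mean total before testing.
#' @param clampA clamp the MAI shrinkage coefficient to at most 1.
#' @param refit refit the error model on the refined matrix in pass two.
#' @param nullScheme see [nullStnDistribution()].
#' @return a validated \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(pFirst = 0.01, bandLow = 0.01, bandHigh = 0.05,
                           pRefined = 0.03, baseline = NA_character_,
                           nIter = 2000L, seed = 1L, normalize = TRUE,
                           clampA = TRUE, refit = TRUE,
                           nullScheme = c("permutation", "baseline-split")) {
    new("PipelineConfig", pFirst = pFirst, bandLow = bandLow,
        bandHigh = bandHigh, pRefined = pRefined,
        baseline = as.character(baseline), nIter = as.integer(nIter),
        seed = as.integer(seed), normalize = normalize, clampA = clampA,
        refit = refit, nullScheme = match.arg(nullScheme))
}

#' First pass: error-model fit and signal-to-noise test of every protein
#'
#' @param x a validated (and, if desired, filtered/normalized)
#'   \linkS4class{SpectralCounts}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param seed RNG seed for the null pool (defaults to the config seed).
#' @return list with \code{fit} (\linkS4class{PlgemFit}), \code{results}
#'   (\linkS4class{StnResults}), and \code{band} (accessions with first-pass
#'   p inside the refinement band).
#' @export
runFirstPass <- function(x, config = PipelineConfig(), seed = config@seed) {
    baseline <- resolveBaseline(x, config@baseline)
    fit <- fitPlgem(x, condition = baseline)
    pool <- nullStnDistribution(x, fit, baseline = baseline,
                                nIter = config@nIter, seed = seed,
                                scheme = config@nullScheme)
    results <- stnPvalues(x, fit, pool, passLabel = "first_pass")
    band <- results$proteinId[results$pValue >= config@bandLow &
                              results$pValue <= config@bandHigh]
    list(fit = fit, results = results, band = band)
}

#' Second pass: moment-adjusted refinement and re-test of the band
#'
#' Replaces the band proteins' counts by their refined values (all other
#' proteins' counts are bit-identical to the first pass), refits the error
#' model on the refined matrix (unless \code{config@refit} is FALSE),
#' rebuilds the null pool from the refined matrix, and recomputes p-values
#' for the band proteins only.
#'
#' @param x the matrix tested in the first pass.
#' @param fit the first-pass \linkS4class{PlgemFit}.
#' @param firstPass the list returned by [runFirstPass()].
#' @param config a \linkS4class{PipelineConfig}.
#' @param seed RNG seed for the rebuilt null pool.
#' @return list with \code{counts} (refined matrix), \code{fit} (pass-two
#'   fit), \code{results} (\linkS4class{StnResults} restricted to the
#'   band) and \code{audit} (refinement records).
#' @export
runRefinementPass <- function(x, fit, firstPass, config = PipelineConfig(),
                              seed = config@seed + 1L) {
    band <- firstPass$band
    ref <- refineProteins(x, fit, band, clamp = config@clampA)
    fit2 <- if (config@refit)
        fitPlgem(ref$counts, condition = resolveBaseline(x, config@baseline))
    else fit
    pool2 <- nullStnDistribution(ref$counts, fit2,
        baseline = resolveBaseline(x, config@baseline),
        nIter = config@nIter, seed = seed, scheme = config@nullScheme)
    all2 <- stnPvalues(ref$counts, fit2, pool2, passLabel = "mai_refined")
    results <- all2[all2$proteinId %in% band, ]
    list(counts = ref$counts, fit = fit2, results = results,
         audit = ref$audit)
}

#' Merge first-pass and refined calls into the final report
#'
#' First-pass calls (p < \code{pFirst}) are frozen: they are never
#' re-assessed. A band protein becomes \code{mai_refined} when its re-test
#' p-value is below \code{pRefined}; everything else is
#' \code{not_significant}. The two significant call sets are disjoint by
#' construction. Fold changes use the condition means of the matrix from
#' each protein's deciding pass, with a 0.5 pseudo-count guarding zero
#' means; they are reported for downstream interpretation and play no role
#' in calling.
#'
#' @param stnFirst first-pass \linkS4class{StnResults} (all proteins).
#' @param stnSecond second-pass \linkS4class{StnResults} (band proteins).
#' @param config a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{DepReport}.
#' @export
mergeCalls <- function(stnFirst, stnSecond, config = PipelineConfig()) {
    p1 <- stnFirst$pValue
    inBand <- p1 >= config@bandLow & p1 <= config@bandHigh
    idx2 <- match(stnFirst$proteinId, stnSecond$proteinId)
    p2 <- stnSecond$pValue[idx2]
    call <- ifelse(p1 < config@pFirst, "first_pass",
            ifelse(inBand & !is.na(p2) & p2 < config@pRefined,
                   "mai_refined", "not_significant"))
    # deciding pass: band proteins were decided on the refined matrix
    useSecond <- inBand & !is.na(p2)
    mA <- ifelse(useSecond, stnSecond$meanA[idx2], stnFirst$meanA)
    mB <- ifelse(useSecond, stnSecond$meanB[idx2], stnFirst$meanB)
    rep <- S4Vectors::DataFrame(
        proteinId = stnFirst$proteinId, meanA = mA, meanB = mB,
        log2fc = log2((mB + 0.5) / (mA + 0.5)),
        pFirst = p1, pRefined = p2, call = call,
        row.names = stnFirst$proteinId)
    rep <- new("DepReport", rep)
    counts <- table(factor(call, levels = c("first_pass", "mai_refined",
                                            "not_significant")))
    S4Vectors::metadata(rep) <- list(
        callCounts = as.list(counts),
        thresholds = list(pFirst = config@pFirst, bandLow = config@bandLow,
                          bandHigh = config@bandHigh,
                          pRefined = config@pRefined))
    rep
}

#' Run the full two-pass spectral-count refinement pipeline
#'
#' Orchestrates: optional run-total normalization; power-law error-model
#' fit on the baseline condition; signal-to-noise test of every protein
#' against a resampling null; moment-adjusted imputation of the proteins in
#' the borderline p-value band; error-model refit and re-test of the band
#' on the refined matrix; merged call report and diagnostics. The whole run
#' is a pure function of (input matrix, configuration): given the same
#' seed, two runs are identical.
#'
#' @param x a validated \linkS4class{SpectralCounts} (apply
#'   [filterIdentifications()] beforehand if flags are present).
#' @param config a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{RefineResult}.
#' @examples
#' sim <- simulateCounts(300, deFraction = 0.1, seed = 42)
#' res <- refineSpectralCounts(sim$counts, PipelineConfig(seed = 42))
#' res
#' @export
refineSpectralCounts <- function(x, config = PipelineConfig()) {
    validObject(x)
    validObject(config)
    seeds <- deriveSeeds(config@seed, 2L)
    if (config@normalize && !isTRUE(S4Vectors::metadata(x)$normalized))
        x <- normalizeCounts(x)
    pass1 <- runFirstPass(x, config, seed = seeds[1L])
    pass2 <- runRefinementPass(x, pass1$fit, pass1, config,
                               seed = seeds[2L])
    report <- mergeCalls(pass1$results, pass2$results, config)
    depIds <- report$proteinId[report$call != "not_significant"]
    loglog <- if (length(depIds) >= 3L) {
        before <- tryCatch(loglogRegression(x, depIds,
            condition = resolveBaseline(x, config@baseline)),
            error = function(e) NULL)
        after <- tryCatch(loglogRegression(pass2$counts, depIds,
            condition = resolveBaseline(x, config@baseline)),
            error = function(e) NULL)
        list(before = before, after = after)
    } else list(before = NULL, after = NULL)
    summary <- list(
        seeds = list(master = config@seed, null1 = seeds[1L],
                     null2 = seeds[2L]),
        logConvention = "natural logarithms; sample SD (n-1) in fits, n-denominator SD in MAI",
        filterSummary = S4Vectors::metadata(x)$filterSummary,
        fitFirst = list(k = pass1$fit@k, c = pass1$fit@c,
                        rSquared = pass1$fit@rSquared),
        fitSecond = list(k = pass2$fit@k, c = pass2$fit@c,
                         rSquared = pass2$fit@rSquared),
        stratifiedFirstPass = stratifiedPvalues(pass1$results, x),
        nBand = length(pass1$band),
        loglogDepBefore = loglog$before, loglogDepAfter = loglog$after,
        callCounts = S4Vectors::metadata(report)$callCounts)
    new("RefineResult", counts = x, refined = pass2$counts,
        fitFirst = pass1$fit, fitSecond = pass2$fit,
        stnFirst = pass1$results, stnSecond = pass2$results,
        maiAudit = pass2$audit, report = report, config = config,
        summary = summary)
}
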