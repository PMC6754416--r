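# draw n replicate counts with mean lambda and target SD exp(cc)*lambda^k.
# Moment matching over a three-way family: the power law of real spectral
# counts is sub-Poisson over most of the abundance range, so under-dispersed
# targets use a binomial, equal-dispersion Poisson, over-dispersed targets a
# negative binomial.
.drawCounts <- function(n, lambda, k, cc) {
    v <- (exp(cc) * lambda^k)^2
    if (v > lambda * (1 + 1e-9)) {
        counts <- stats::rnbinom(n, mu = lambda,
                                 size = lambda^2 / (v - lambda))
        family <- "nbinom"
    } else if (v > lambda * (1 - 1e-9)) {
        counts <- stats::rpois(n, lambda)
        family <- "poisson"
    } else {
        trials <- max(1L, as.integer(round(lambda^2 / (lambda - v))))
        counts <- stats::rbinom(n, trials, min(1, lambda / trials))
        family <- "binomial"
    }
    list(counts = counts, family = family)
}

#' Simulate a two-condition spectral-count experiment
#'
#' Generates integer counts whose replicate noise follows the power-law
#' error model \eqn{SD = e^{c} \lambda^{k}}, with true mean abundances
#' drawn log-uniformly across the given range (spanning the low-abundance,
#' mean < 5, and high-abundance strata), an optional fraction of truly
#' differential proteins, and zero-inflation ("dropout") of low-abundance
#' observations emulating the undersampling bias of data-dependent
#' acquisition. Counts are drawn from a moment-matched binomial / Poisson /
#' negative-binomial family depending on whether the target variance is
#' below, at, or above the mean (the default power law is sub-Poisson over
#' almost the whole abundance range). Fully reproducible from the seed.
#'
#' The dropout mechanism deliberately violates the power law below the
#' dropout threshold -- that excess low-abundance variance is precisely the
#' phenomenon the refinement pipeline targets.
#'
#' @param nProteins number of proteins (>= 10).
#' @param nReplicates replicate runs per condition (default 3).
#' @param abundanceRange log-uniform range of true mean counts
#'   (default 0.5 to 500).
#' @param kTrue,cTrue power-law noise parameters (defaults 0.31, -0.33).
#' @param deFraction fraction of truly differential proteins; exactly
#'   \code{round(deFraction * nProteins)} proteins are flagged.
#' @param log2fc effect magnitude for differential proteins; direction is
#'   randomized per protein with balanced signs.
#' @param deLowOnly restrict differential proteins to the low-abundance
#'   stratum (true baseline mean below \code{dropoutBelow}).
#' @param dropout probability that an observation of a protein whose true
#'   condition mean is below \code{dropoutBelow} is recorded as 0.
#' @param dropoutBelow abundance threshold for dropout (default 5).
#' @param conditions the two condition labels (default HG, GD; the first is
#'   the baseline).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with \code{counts} (a \linkS4class{SpectralCounts}) and
#'   \code{truth} (\linkS4class{DataFrame}: \code{proteinId},
#'   \code{lambdaA}, \code{lambdaB}, \code{isDe}, \code{trueLog2fc},
#'   \code{family}).
#' @export
simulateCounts <- function(nProteins, nReplicates = 3L,
                           abundanceRange = c(0.5, 500),
                           kTrue = 0.31, cTrue = -0.33,
                           deFraction = 0, log2fc = 1.5,
                           deLowOnly = FALSE,
                           dropout = 0.1, dropoutBelow = 5,
                           conditions = c("HG", "GD"), seed = 1L) {
    stopifnot(nProteins >= 10L, nReplicates >= 2L, kTrue >= 0,
              deFraction >= 0, deFraction <= 1, dropout >= 0, dropout <= 1,
              length(conditions) == 2L)
    withSeed(seed, {
        lambdaA <- exp(stats::runif(nProteins, log(abundanceRange[1L]),
                                    log(abundanceRange[2L])))
        nDe <- round(deFraction * nProteins)
        pool <- if (deLowOnly) which(lambdaA < dropoutBelow)
                else seq_len(nProteins)
        if (nDe > length(pool))
            stop(sprintf("cannot place %d differential proteins in a pool of %d",
                         nDe, length(pool)))
        deIdx <- sample(pool, nDe)
        sign <- rep_len(c(1, -1), nDe)[sample.int(max(nDe, 1L), nDe)]
        trueFc <- numeric(nProteins)
        trueFc[deIdx] <- sign * log2fc
        lambdaB <- lambdaA * 2^trueFc
        cnt <- matrix(0, nProteins, 2L * nReplicates)
        family <- character(nProteins)
        lam <- cbind(lambdaA, lambdaB)
        for (i in seq_len(nProteins)) {
            for (j in 1:2) {
                cols <- seq_len(nReplicates) + (j - 1L) * nReplicates
                d <- .drawCounts(nReplicates, lam[i, j], kTrue, cTrue)
                obs <- d$counts
                if (dropout > 0 && lam[i, j] < dropoutBelow)
                    obs <- obs * stats::rbinom(nReplicates, 1L, 1 - dropout)
                cnt[i, cols] <- obs
                family[i] <- d$family
            }
        }
        ids <- sprintf("SIM%04d", seq_len(nProteins))
        rownames(cnt) <- ids
        colnames(cnt) <- paste(rep(conditions, each = nReplicates),
                               rep(seq_len(nReplicates), 2L), sep = "_")
        sc <- SpectralCounts(cnt, rep(conditions, each = nReplicates))
        truth <- S4Vectors::DataFrame(
            proteinId = ids, lambdaA = lambdaA, lambdaB = lambdaB,
            isDe = seq_len(nProteins) %in% deIdx, trueLog2fc = trueFc,
            family = family, row.names = ids)
        list(counts = sc, truth = truth)
    })
}

#' Score pipeline calls against simulation truth
#'
#' Confusion-matrix summaries for the merged calls and for the first-pass
#' calls alone, overall and within abundance strata (true baseline mean
#' below / at-or-above the threshold). Sensitivity is the fraction of truly
#' differential proteins called; the false-positive rate is the fraction of
#' null proteins called.
#'
#' @param report a \linkS4class{DepReport}.
#' @param truth the truth table from [simulateCounts()].
#' @param thresholdMean abundance stratum boundary on the true baseline
#'   mean (default 5).
#' @return list with elements \code{merged} and \code{firstPass}, each a
#'   data.frame of stratum-wise and overall \code{n}, \code{nDe},
#'   \code{sensitivity} and \code{fpr}.
#' @export
evaluateCalls <- function(report, truth, thresholdMean = 5) {
    if (!setequal(report$proteinId, truth$proteinId))
        stop("report and truth protein identifiers do not match")
    truth <- truth[match(report$proteinId, truth$proteinId), ]
    isDe <- truth$isDe
    strata <- list(
        overall = rep(TRUE, nrow(truth)),
        low = truth$lambdaA < thresholdMean,
        high = truth$lambdaA >= thresholdMean)
    score <- function(called) {
        rows <- lapply(names(strata), function(s) {
            sel <- strata[[s]]
            data.frame(stratum = s, n = sum(sel), nDe = sum(isDe & sel),
                sensitivity = if (any(isDe & sel))
                    sum(called & isDe & sel) / sum(isDe & sel) else NA_real_,
                fpr = if (any(!isDe & sel))
                    sum(called & !isDe & sel) / sum(!isDe & sel) else
                    NA_real_)
        })
        do.call(rbind, rows)
    }
    list(merged = score(report$call != "not_significant"),
         firstPass = score(report$call == "first_pass"))
}
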