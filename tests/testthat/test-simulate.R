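test_that("the generator is reproducible and honors its contract", {
    a <- simulateCounts(50, deFraction = 0.2, seed = 10)
    b <- simulateCounts(50, deFraction = 0.2, seed = 10)
    expect_identical(scCounts(a$counts), scCounts(b$counts))
    expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
    c <- simulateCounts(50, deFraction = 0.2, seed = 11)
    expect_false(identical(scCounts(a$counts), scCounts(c$counts)))

    # exactly round(deFraction * n) differential proteins, balanced signs
    t2 <- simulateCounts(200, deFraction = 0.13, seed = 4)$truth
    expect_identical(sum(t2$isDe), as.integer(round(0.13 * 200)))
    expect_lte(abs(sum(sign(t2$trueLog2fc))), 1)
    expect_true(all(abs(t2$trueLog2fc[t2$isDe]) == 1.5))
    expect_true(all(t2$lambdaB[t2$isDe] ==
                    t2$lambdaA[t2$isDe] * 2^t2$trueLog2fc[t2$isDe]))
    expect_true(all(t2$lambdaB[!t2$isDe] == t2$lambdaA[!t2$isDe]))

    # raw counts are non-negative integers
    cnt <- scCounts(a$counts)
    expect_true(all(cnt >= 0))
    expect_true(all(cnt == round(cnt)))

    # null configuration has no differential proteins at all
    t0 <- simulateCounts(40, deFraction = 0, seed = 1)$truth
    expect_identical(sum(t0$isDe), 0L)

    # low-only placement keeps effects below the abundance threshold
    tl <- simulateCounts(300, deFraction = 0.1, deLowOnly = TRUE,
                         seed = 2)$truth
    expect_true(all(tl$lambdaA[tl$isDe] < 5))
})

test_that("degenerate noise settings yield identical replicates", {
    # k = 0, c -> -inf approximated by a tiny SD target: binomial matching
    # with var ~ 0 makes replicates equal to the (rounded) mean
    sim <- simulateCounts(20, kTrue = 0, cTrue = -12, dropout = 0,
                          abundanceRange = c(20, 200), seed = 5)
    cnt <- scCounts(sim$counts)
    spread <- apply(cnt[, 1:3], 1, function(v) diff(range(v)))
    # integer moment-matching leaves at most rounding-scale wiggle
    expect_lte(max(spread), 2)
    expect_lt(mean(spread), 0.5)
})

test_that("dropout recreates the low-abundance excess-variance pattern", {
    spreadByStratum <- function(dropout) {
        sim <- simulateCounts(1500, dropout = dropout, seed = 17)
        fit <- fitPlgem(sim$counts)
        vd <- varianceDiagnostics(sim$counts, fit)
        truth <- sim$truth[match(vd$proteinId, sim$truth$proteinId), ]
        low <- truth$lambdaA < 5
        list(lowSpread = mean(abs(log(vd$ratio[low])), na.rm = TRUE),
             fracExcessLow = mean(vd$ratio[low] < 1, na.rm = TRUE),
             fracExcessHigh = mean(vd$ratio[!low] < 1, na.rm = TRUE))
    }
    with <- spreadByStratum(0.25)
    without <- spreadByStratum(0)
    # dropout widens the measured-vs-expected discrepancy where it acts
    expect_gt(with$lowSpread, without$lowSpread)
    # and makes low-abundance proteins exceed the model SD more often than
    # high-abundance ones -- the undersampling signature
    expect_gt(with$fracExcessLow, with$fracExcessHigh)
    expect_lt(abs(without$fracExcessLow - without$fracExcessHigh), 0.05)
})

test_that("the moment-matched family reproduces the configured noise law", {
    sim <- simulateCounts(2000, dropout = 0, seed = 1)
    fit <- fitPlgem(sim$counts)
    # integer triplicates attenuate the observed slope; the recovered
    # parameters must still sit near the configured law
    expect_lt(abs(fit@k - 0.31), 0.06)
    expect_lt(abs(fit@c - (-0.33)), 0.10)
    # an over-dispersed law (super-Poisson) exercises the NB branch
    simNb <- simulateCounts(300, kTrue = 0.8, cTrue = 0.2, dropout = 0,
                            abundanceRange = c(5, 200), seed = 2)
    expect_true(any(simNb$truth$family == "nbinom"))
    fitNb <- fitPlgem(simNb$counts)
    expect_lt(abs(fitNb@k - 0.8), 0.1)
})

test_that("call scoring equals a brute-force confusion recount", {
    sim <- simulateCounts(200, deFraction = 0.25, seed = 20)
    res <- refineSpectralCounts(sim$counts, PipelineConfig(seed = 20))
    rep <- depReport(res)
    ev <- evaluateCalls(rep, sim$truth)
    truth <- sim$truth[match(rep$proteinId, sim$truth$proteinId), ]
    called <- rep$call != "not_significant"
    expect_equal(ev$merged$sensitivity[1],
                 sum(called & truth$isDe) / sum(truth$isDe))
    expect_equal(ev$merged$fpr[1],
                 sum(called & !truth$isDe) / sum(!truth$isDe))
    onlyFirst <- rep$call == "first_pass"
    expect_equal(ev$firstPass$sensitivity[1],
                 sum(onlyFirst & truth$isDe) / sum(truth$isDe))
    low <- truth$lambdaA < 5
    expect_equal(ev$merged$sensitivity[2],
                 sum(called & truth$isDe & low) / sum(truth$isDe & low))
    # a perfect report scores sensitivity 1 and FPR 0
    perfect <- rep
    perfect$call <- ifelse(truth$isDe, "first_pass", "not_significant")
    evp <- evaluateCalls(perfect, sim$truth)
    expect_equal(evp$merged$sensitivity[1], 1)
    expect_equal(evp$merged$fpr[1], 0)
    # mismatched identifiers are an error
    badTruth <- sim$truth
    badTruth$proteinId[1] <- "other"
    expect_error(evaluateCalls(rep, badTruth), "identifiers")
})
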