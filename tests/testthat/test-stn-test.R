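test_that("the signal-to-noise statistic behaves as its closed form", {
    expect_equal(stnStatistic(10, 5, 2, 1.5), 5 / 3.5)
    expect_equal(stnStatistic(7, 7, 1, 2), 0)
    # antisymmetry under condition swap
    expect_equal(stnStatistic(4, 9, 1.2, 0.8),
                 -stnStatistic(9, 4, 0.8, 1.2))
    expect_error(stnStatistic(1, 2, 0, 0), "positive")
})

test_that("exhaustive null pools equal independent enumeration", {
    x <- toyCounts(matrix(c(
         3,  5,  9,   2,  4,  6,
        20, 22, 25,  30, 28, 26,
         0,  1,  0,   2,  0,  1,
        50, 48, 55,  47, 52, 51), 4, 6, byrow = TRUE))
    fit <- fitPlgem(x)
    cnt <- scCounts(x)

    nb <- nullStnDistribution(x, fit, scheme = "baseline-split")
    expect_true(attr(nb, "exhaustive"))
    expect_identical(attr(nb, "nSplits"), 6L)
    expect_equal(sort(nb), sort(oracleBaselineNull3(cnt, 1:3, fit@k, fit@c)))

    np <- nullStnDistribution(x, fit, scheme = "permutation")
    expect_identical(attr(np, "nSplits"), 20L)
    expect_equal(sort(np), sort(oraclePermNull33(cnt, fit@k, fit@c)))

    # identical baseline replicates -> every baseline-split null value is 0
    y <- toyCounts(matrix(c(rep(c(4, 4, 4), 4), rpois(12, 9)), 4, 6))
    nz <- nullStnDistribution(y, fitPlgem(x), scheme = "baseline-split")
    expect_true(all(nz == 0))
})

test_that("Monte-Carlo pools converge to the exhaustive pool", {
    x <- toyCounts(matrix(c(
         3,  5,  9,   2,  4,  6,
        20, 22, 25,  30, 28, 26,
         1,  1,  2,   2,  0,  1,
        50, 48, 55,  47, 52, 51), 4, 6, byrow = TRUE))
    fit <- fitPlgem(x)
    for (scheme in c("baseline-split", "permutation")) {
        ex <- nullStnDistribution(x, fit, scheme = scheme)
        mc <- nullStnDistribution(x, fit, scheme = scheme,
                                  nIter = 10000, seed = 77,
                                  exhaustive = FALSE)
        expect_false(attr(mc, "exhaustive"))
        # p-values computed from the two pools agree within MC error
        pe <- stnPvalues(x, fit, ex)$pValue
        pm <- stnPvalues(x, fit, mc)$pValue
        expect_lt(max(abs(pe - pm)), 0.03)
        # reproducible given the seed
        mc2 <- nullStnDistribution(x, fit, scheme = scheme,
                                   nIter = 10000, seed = 77,
                                   exhaustive = FALSE)
        expect_identical(as.numeric(mc), as.numeric(mc2))
    }
    expect_error(nullStnDistribution(x, fit, nIter = 50, exhaustive = FALSE),
                 "seed")
})

test_that("pooled null is symmetric about zero under exchangeability", {
    sim <- simulateCounts(60, seed = 14)
    fit <- fitPlgem(sim$counts)
    pool <- nullStnDistribution(sim$counts, fit, scheme = "baseline-split",
                                nIter = 10000, seed = 5, exhaustive = FALSE)
    expect_lt(abs(momentSkewness(pool)), 0.1)
})

test_that("empirical p-values equal the brute-force tail recount", {
    x <- toyCounts()
    fit <- fitPlgem(x)
    pool <- nullStnDistribution(x, fit)
    res <- stnPvalues(x, fit, pool)
    obs <- stnStatistic(res$meanA, res$meanB, res$sdModelA, res$sdModelB)
    expect_equal(res$stn, obs)
    expect_equal(res$pValue, oracleTailP(pool, res$stn))
    # stn = 0 -> p = 1; |stn| beyond the pool -> p = 0
    expect_equal(oracleTailP(pool, 0), 1)
    big <- max(abs(pool)) + 1
    expect_equal(unname(oracleTailP(pool, big)), 0)
    res2 <- stnPvalues(x, fit, pool, pseudocount = TRUE)
    expect_true(all(res2$pValue > 0))
    expect_equal(res2$pValue,
                 (oracleTailP(pool, res$stn) * length(pool) + 1) /
                     (length(pool) + 1))
})

test_that("p-values are monotone in |stn| and invariant to row order", {
    sim <- simulateCounts(50, seed = 2)
    x <- sim$counts
    fit <- fitPlgem(x)
    pool <- nullStnDistribution(x, fit)
    res <- stnPvalues(x, fit, pool)
    o <- order(abs(res$stn))
    expect_true(all(diff(res$pValue[o]) <= 0))

    perm <- sample(nrow(x))
    resPerm <- stnPvalues(x[perm, ], fit, nullStnDistribution(x[perm, ], fit))
    expect_equal(resPerm[res$proteinId, "pValue"], res$pValue)

    # relabeling replicates within a condition leaves exhaustive p unchanged
    shuffled <- x[, c(3, 1, 2, 4, 6, 5)]
    resShuf <- stnPvalues(shuffled, fit, nullStnDistribution(shuffled, fit))
    expect_equal(resShuf$pValue, res$pValue)
})

test_that("null simulations give approximately uniform p-values", {
    sim <- simulateCounts(600, deFraction = 0, seed = 31)
    x <- normalizeCounts(sim$counts)
    fit <- fitPlgem(x)
    res <- stnPvalues(x, fit, nullStnDistribution(x, fit))
    frac <- mean(res$pValue < 0.05)
    se <- sqrt(0.05 * 0.95 / 600)
    expect_lt(abs(frac - 0.05), 3 * se)
    # both abundance strata are near-uniform too
    strat <- stratifiedPvalues(res, x)
    expect_true(all(abs(strat$meanP - 0.5) < 0.1))
})

test_that("stratified summaries split and average correctly", {
    x <- toyCounts(matrix(c(
        1, 1, 2,  1, 0, 1,      # mean < 5
        30, 28, 26, 29, 31, 30, # mean >= 5
        2, 2, 2,  2, 2, 2,
        40, 44, 48, 50, 40, 42), 4, 6, byrow = TRUE))
    fit <- fitPlgem(x)
    res <- stnPvalues(x, fit, nullStnDistribution(x, fit))
    strat <- stratifiedPvalues(res, x)
    expect_identical(strat$n, c(2L, 2L))
    low <- rowMeans(scCounts(x)) < 5
    expect_equal(strat$meanP, c(mean(res$pValue[low]),
                                mean(res$pValue[!low])))
    # constant p-values: both strata report that constant
    resConst <- res
    resConst$pValue <- rep(0.5, 4)
    expect_equal(stratifiedPvalues(resConst, x)$meanP, c(0.5, 0.5))
    # single-stratum input: the empty stratum is absent, not an error
    xl <- x[low, ]
    resLow <- res[low, ]
    expect_identical(nrow(stratifiedPvalues(resLow, xl)), 1L)
})
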