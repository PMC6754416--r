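test_that("skewness matches direct moment computation", {
    expect_equal(momentSkewness(c(3, 3, 3)), 0)
    # (1,2,9): m3 = 30, m2 = 38/3
    expect_equal(momentSkewness(c(1, 2, 9)), 30 / (38 / 3)^1.5)
    expect_equal(momentSkewness(c(1, 2, 9)), 0.6655, tolerance = 1e-4)
    # reflection antisymmetry for arbitrary vectors and constants
    set.seed(4)
    for (i in 1:20) {
        v <- rpois(sample(3:8, 1), 6)
        cst <- runif(1, -5, 5)
        expect_equal(momentSkewness(cst - v), -momentSkewness(v))
    }
    expect_error(momentSkewness(c(1, 2)), "at least 3")
})

test_that("shrinkage coefficient is the clamped SD ratio", {
    expect_equal(shrinkageCoefficient(2.4, 2.4), 1)
    expect_equal(shrinkageCoefficient(1.78, 3.56), 0.5)
    expect_equal(shrinkageCoefficient(10, 1), 1)
    expect_equal(shrinkageCoefficient(10, 1, clamp = FALSE), 10)
    expect_error(shrinkageCoefficient(1, 0), "positive")
})

test_that("moment adjustment reproduces the worked shrinkage cases", {
    # right-skewed (1,2,9): mean 4, sigma_w = sqrt(38/3); a-hat 0.5 shrinks
    # the largest value to 9*0.5 + 4*0.5 = 6.5
    sw <- sqrt(38 / 3)
    adj <- maiAdjust(c(1, 2, 9), sigmaX = 0.5 * sw)
    expect_equal(adj$refined, c(1, 2, 6.5))
    expect_identical(adj$record$adjustedIndex, "largest")
    expect_equal(adj$record$aHatUsed, 0.5)
    expect_gt(adj$record$skewness, 0)

    # left-skewed mirror (1,8,9): mean 6, smallest -> 1*0.5 + 6*0.5 = 3.5
    sw2 <- sqrt(mean((c(1, 8, 9) - 6)^2))
    adj2 <- maiAdjust(c(1, 8, 9), sigmaX = 0.5 * sw2)
    expect_equal(adj2$refined, c(3.5, 8, 9))
    expect_identical(adj2$record$adjustedIndex, "smallest")

    # a-hat = 1 leaves values unchanged regardless of skew
    adj3 <- maiAdjust(c(1, 2, 9), sigmaX = 2 * sw)  # raw ratio 2, clamped
    expect_equal(adj3$refined, c(1, 2, 9))
    expect_equal(adj3$record$aHatRaw, 2)
    expect_equal(adj3$record$aHatUsed, 1)

    # symmetric and constant vectors are fixed points
    expect_equal(maiAdjust(c(2, 3, 4), 1)$refined, c(2, 3, 4))
    expect_identical(maiAdjust(c(5, 5, 5), 1)$record$adjustedIndex, "none")
    # unclamped literal formula moves the extreme away from the mean
    adj4 <- maiAdjust(c(1, 2, 9), sigmaX = 2 * sw, clamp = FALSE)
    expect_equal(adj4$refined[3], 9 * 2 + 4 * (1 - 2))
})

test_that("adjustment properties hold over a large random sweep", {
    set.seed(123)
    nCases <- 10000
    sdN <- function(x) sqrt(mean((x - mean(x))^2))
    adjusted <- 0
    bad <- list(multi = 0, negative = 0, variance = 0, convex = 0,
                order = 0, fixedPoint = 0)
    for (i in seq_len(nCases)) {
        n <- sample(3:6, 1)
        v <- switch(sample(3, 1),
                    rpois(n, exp(runif(1, log(0.5), log(120)))),
                    round(rgamma(n, shape = 2, scale = 10)),
                    sample(0:5, n, replace = TRUE))
        sigmaX <- runif(1, 0.05, 6)
        adj <- maiAdjust(v, sigmaX)
        r <- adj$refined
        if (sum(r != v) > 1) bad$multi <- bad$multi + 1
        if (any(r < 0)) bad$negative <- bad$negative + 1
        if (adj$record$adjustedIndex != "none" &&
            adj$record$aHatUsed < 1) {
            adjusted <- adjusted + 1
            if (sdN(r) >= sdN(v)) bad$variance <- bad$variance + 1
            pos <- which(r != v)
            lo <- min(v[pos], mean(v)); hi <- max(v[pos], mean(v))
            if (r[pos] < lo - 1e-12 || r[pos] > hi + 1e-12)
                bad$convex <- bad$convex + 1
            # sorted inputs stay sorted unless the audit flags the
            # extreme-shrinkage crossing
            if (is.unsorted(r[order(v)]) && !adj$record$orderViolated)
                bad$order <- bad$order + 1
        }
        # re-adjusting a symmetric vector is a fixed point
        if (abs(adj$record$skewness) <= 1e-12 &&
            !isTRUE(all.equal(maiAdjust(r, sigmaX)$refined, r)))
            bad$fixedPoint <- bad$fixedPoint + 1
    }
    expect_identical(unique(unlist(bad)), 0)
    # the sweep must actually have exercised the adjustment path
    expect_gt(adjusted, nCases / 4)
})

test_that("per-protein refinement treats the two conditions independently", {
    x <- toyCounts(matrix(c(
        1, 2, 9,   4, 4, 4,
        3, 3, 3,   1, 8, 9,
        10, 11, 12, 10, 12, 14,
        0, 0, 0,   5, 6, 7), 4, 6, byrow = TRUE))
    # a fixed error model supplies sigma_x well below these vectors'
    # measured SDs, so shrinkage genuinely happens
    fit <- new("PlgemFit", k = 0.31, c = -0.33, rSquared = NA_real_,
               residualSd = NA_real_, nPoints = 3L, condition = "HG",
               scope = "condition", nBins = 0L)
    r1 <- refineProtein(x, fit, "P1")
    expect_identical(r1$adjustedIndex, c("largest", "none"))
    r2 <- refineProtein(x, fit, "P2")
    expect_identical(r2$adjustedIndex, c("none", "smallest"))
    # zero-mean condition is recorded, not adjusted
    r4 <- refineProtein(x, fit, "P4")
    expect_identical(r4$adjustedIndex[1], "none")
    expect_match(r4$note[1], "zero condition mean")
    # refined SD never exceeds measured SD, per condition
    sdN <- function(v) sqrt(mean((v - mean(v))^2))
    for (pid in rownames(x)) {
        rr <- refineProtein(x, fit, pid)
        for (j in 1:2)
            expect_lte(sdN(unlist(rr$refined[j])),
                       sdN(unlist(rr$w[j])) + 1e-12)
    }
    expect_error(refineProtein(x, fit, "nope"), "not found")

    # batch refinement touches exactly the requested rows
    ref <- refineProteins(x, fit, c("P1", "P2"))
    cnt0 <- scCounts(x); cnt1 <- scCounts(ref$counts)
    expect_identical(cnt0[c("P3", "P4"), ], cnt1[c("P3", "P4"), ])
    expect_false(identical(cnt0["P1", ], cnt1["P1", ]))
    expect_identical(nrow(ref$audit), 4L)
    # empty request: matrix unchanged, zero-row audit
    ref0 <- refineProteins(x, fit, character(0))
    expect_identical(scCounts(ref0$counts), cnt0)
    expect_identical(nrow(ref0$audit), 0L)
})
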