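# fixtures and independent oracles shared across test files

# small deterministic count matrix: 2 conditions x 3 replicates
toyCounts <- function(values = NULL, nProteins = 4L) {
    if (is.null(values)) {
        set.seed(99)
        values <- matrix(rpois(nProteins * 6L, lambda = 12), nProteins, 6L)
    }
    rownames(values) <- paste0("P", seq_len(nrow(values)))
    colnames(values) <- paste0(rep(c("HG", "GD"), each = 3L), "_", 1:3)
    SpectralCounts(values, rep(c("HG", "GD"), each = 3L))
}

# independent tail-fraction oracle (plain recount, no sorting tricks)
oracleTailP <- function(nullPool, observed)
    vapply(observed, function(o) mean(abs(nullPool) >= abs(o)), 0)

# independent model SD (direct formula)
oracleModelSd <- function(k, c, m) exp(c) * m^k

# independent null pool for the baseline-split scheme on 3 baseline
# replicates: the 6 ordered 1-vs-2 splits, written out literally
oracleBaselineNull3 <- function(cnt, baselineCols, k, c) {
    sdm <- function(m) exp(c) * pmax(m, 0.5)^k
    out <- c()
    for (solo in baselineCols) {
        rest <- setdiff(baselineCols, solo)
        ma <- cnt[, solo]
        mb <- (cnt[, rest[1]] + cnt[, rest[2]]) / 2
        out <- c(out, unname((ma - mb) / (sdm(ma) + sdm(mb))),
                      unname((mb - ma) / (sdm(mb) + sdm(ma))))
    }
    out
}

# independent null pool for the permutation scheme on 3+3 runs: all 20
# choose(6,3) ordered splits
oraclePermNull33 <- function(cnt, k, c) {
    sdm <- function(m) exp(c) * pmax(m, 0.5)^k
    out <- c()
    for (aset in combn(6, 3, simplify = FALSE)) {
        ma <- rowMeans(cnt[, aset, drop = FALSE])
        mb <- rowMeans(cnt[, setdiff(1:6, aset), drop = FALSE])
        out <- c(out, unname((ma - mb) / (sdm(ma) + sdm(mb))))
    }
    out
}
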