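# shared numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# population (n-denominator) standard deviation; the MAI machinery uses this,
# the error-model fit uses stats::sd (n-1)
sdPop <- function(x) sqrt(mean((x - mean(x))^2))

# run code with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# derive n child seeds from one master seed (kept below .Machine$integer.max)
deriveSeeds <- function(seed, n)
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))

# columns of the runs belonging to one condition
conditionColumns <- function(x, condition) {
    cond <- runConditions(x)
    if (!condition %in% levels(cond))
        stop(sprintf("unknown condition '%s' (have: %s)", condition,
                     paste(levels(cond), collapse = ", ")))
    which(cond == condition)
}

# resolve NA/NULL baseline to the first condition level
resolveBaseline <- function(x, baseline) {
    if (is.null(baseline) || is.na(baseline)) conditionNames(x)[1L]
    else {
        conditionColumns(x, baseline)  # validates
        baseline
    }
}
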