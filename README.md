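# scRefine

Two-pass label-free protein quantification from LC-MS/MS spectral counts,
with a statistical rescue of low-abundance proteins.

## The problem

Spectral counting — the number of MS/MS spectra matched to a protein per run
— is the simplest label-free proxy for protein abundance. But data-dependent
acquisition samples precursors by intensity, so low-abundance proteins
(mean spectral count below ~5) are counted erratically across replicate
runs. Their inflated replicate variance pushes otherwise-real expression
differences out of statistical significance, and a conventional analysis
silently drops exactly the regulatory proteins one often cares about.

## The method

**Pass 1 — power-law error model + signal-to-noise test.** Replicate noise
of spectral counts follows a power law: the standard deviation *s* and mean
*x̄* of a protein's replicates satisfy

```
ln(s) = k · ln(x̄) + c + ε
```

fitted by ordinary least squares over all proteins of the baseline
condition (the PLGEM of the proteomics literature). Each protein is scored
with the model-based signal-to-noise statistic

```
STN = (x̄_A − x̄_B) / (σ̂(x̄_A) + σ̂(x̄_B)),     σ̂(m) = e^c · m^k
```

and given an empirical two-sided p-value against a pooled resampling null
(splits of the replicate runs into pseudo-conditions; exhaustively
enumerated for triplicates, so the run is deterministic). Proteins with
p < 0.01 are confident differential calls.

**Pass 2 — moment-adjusted imputation (MAI) of the borderline band.**
Proteins with 0.01 ≤ p ≤ 0.05 get a measurement-error correction. Within
each condition, if the replicate triple W₁ ≤ … ≤ Wₙ is skewed, the extreme
order statistic on the skewed side is treated as mis-measured and replaced
by the convex combination

```
X̂ = W·â + W̄·(1 − â),      â = (σ̂ₓ² / σ̂_w²)^{1/2}  (clamped to ≤ 1)
```

where σ̂_w is the measured (n-denominator) SD and σ̂ₓ the model SD at the
replicate mean — i.e. the noisier the protein relative to the global error
model, the harder its outlying replicate is shrunk toward the mean. The
error model is refit on the refined matrix, band proteins are re-tested,
and those reaching p < 0.03 are merged with the pass-1 calls.

The package also ships variance diagnostics (σ-expected/σ-measured ratios,
stratified p-value summaries, before/after log-log regressions) and a
synthetic-data generator that reproduces the abundance-dependent noise law
and the low-abundance dropout structure, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(scRefine)

# 2,000 proteins, 20% truly differential (|log2FC| = 1.5) all at low
# abundance, 10% dropout below mean 5 -- the hard regime
sim <- simulateCounts(2000, deFraction = 0.2, log2fc = 1.5,
                      deLowOnly = TRUE, dropout = 0.1, seed = 1)
res <- refineSpectralCounts(sim$counts, PipelineConfig(seed = 1))
res
#> Two-pass spectral-count refinement result
#>   2000 proteins tested; calls: 112 first-pass, 84 MAI-refined, 1804 not significant
#>   pass-1 fit: k = 0.3176, c = -0.7684 (R^2 0.162); pass-2 fit: k = 0.3218, c = -0.7892 (R^2 0.166)
#>   112 proteins in the refinement band

evaluateCalls(depReport(res), sim$truth)$merged
#>   stratum    n nDe sensitivity     fpr
#> 1 overall 2000 400       0.458 0.00813
#> 2     low  669 400       0.458 0.02230
#> 3    high 1331   0          NA 0.00526
```

The first pass alone finds 112 differential proteins (sensitivity 0.28 on
the 400 planted low-abundance effects); the refinement pass rescues 84
more, lifting low-abundance sensitivity to 0.458 — the ~75% gain in
quantifiable proteins that motivates the second pass. `depReport(res)`
holds the per-protein table (means, log2 fold change, both p-values, the
call), `maiAudit(res)` the per-condition shrinkage records, and
`writeRunReport(res, "out/")` serializes everything as TSV + JSON.

Real data enter through two plain text tables:

```r
x <- readSpectralCounts("counts.tsv", "design.tsv")  # protein x run; run -> condition
x <- filterIdentifications(x)                        # drop keratins & decoys
res <- refineSpectralCounts(x, PipelineConfig(baseline = "HG", seed = 1))
```

or through the CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","screfine.R",package="scRefine"))') \
    run --counts counts.tsv --design design.tsv --out results --seed 1
```

(subcommands: `run`, `simulate`, `diagnose`; every flag can live in a
`--config key=value` file).

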