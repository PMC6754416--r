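# flatten NumericList columns for TSV serialization
.flattenForTsv <- function(df) {
    df <- as.data.frame(df)
    for (nm in names(df))
        if (is.list(df[[nm]]))
            df[[nm]] <- vapply(df[[nm]], function(v)
                paste(signif(v, 8), collapse = ","), "")
    df
}

.writeTsv <- function(df, path)
    utils::write.table(.flattenForTsv(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

#' Write the machine-readable run report
#'
#' Serializes a pipeline result into a directory: \code{dep_report.tsv},
#' \code{stn_pass1.tsv}, \code{stn_pass2.tsv}, \code{mai_audit.tsv},
#' \code{diagnostics.tsv} (first-pass variance diagnostics) and
#' \code{report.json} (configuration echo, seeds, log convention, fit
#' parameters of both passes, stratified p-value summary, before/after
#' log-log regression over the significant set, and call counts). Two runs
#' with identical input, configuration and seed produce byte-identical
#' tables.
#'
#' @param result a \linkS4class{RefineResult}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeRunReport <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("dep_report.tsv", "stn_pass1.tsv",
                              "stn_pass2.tsv", "mai_audit.tsv",
                              "diagnostics.tsv", "report.json"))
    .writeTsv(result@report, paths[1L])
    .writeTsv(result@stnFirst, paths[2L])
    .writeTsv(result@stnSecond, paths[3L])
    .writeTsv(result@maiAudit, paths[4L])
    .writeTsv(varianceDiagnostics(result@counts, result@fitFirst),
              paths[5L])
    cfg <- result@config
    json <- list(
        config = list(pFirst = cfg@pFirst, bandLow = cfg@bandLow,
            bandHigh = cfg@bandHigh, pRefined = cfg@pRefined,
            baseline = cfg@baseline, nIter = cfg@nIter, seed = cfg@seed,
            normalize = cfg@normalize, clampA = cfg@clampA,
            refit = cfg@refit, nullScheme = cfg@nullScheme),
        summary = result@summary)
    writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                                null = "null", dataframe = "rows"),
               paths[6L])
    invisible(paths)
}
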