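#' Construct a SpectralCounts object
#'
#' @param counts numeric matrix of non-negative spectral counts, proteins in
#'   rows (rownames = unique accessions), runs in columns.
#' @param condition character or factor of length \code{ncol(counts)}
#'   assigning every run to one of exactly two conditions; each condition
#'   needs at least two replicate runs.
#' @param description optional per-protein free-text description.
#' @param isContaminant,isDecoy optional logical flags per protein
#'   (keratin-family contaminants and reverse-database decoys).
#' @return a validated \linkS4class{SpectralCounts}.
#' @examples
#' m <- matrix(rpois(18, 10), 3, 6,
#'             dimnames = list(paste0("P", 1:3), paste0("run", 1:6)))
#' SpectralCounts(m, rep(c("HG", "GD"), each = 3))
#' @export
SpectralCounts <- function(counts, condition, description = NULL,
                           isContaminant = NULL, isDecoy = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("run", seq_len(ncol(counts)))
    if (length(condition) != ncol(counts))
        stop("'condition' must name the condition of every run (column)")
    cond <- if (is.factor(condition)) droplevels(condition)
            else factor(condition, levels = unique(condition))
    cd <- S4Vectors::DataFrame(run = colnames(counts), condition = cond,
                               row.names = colnames(counts))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(description)) rd$description <- as.character(description)
    if (!is.null(isContaminant)) rd$isContaminant <- as.logical(isContaminant)
    if (!is.null(isDecoy)) rd$isDecoy <- as.logical(isDecoy)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
    new("SpectralCounts", se)
}

.readTable <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
}

#' Read a count matrix and its design table
#'
#' The counts file (TSV or CSV by extension, header row) must have a
#' \code{protein_id} first column, optional \code{description},
#' \code{is_contaminant} and \code{is_decoy} columns, and one numeric column
#' per run. The design file maps every \code{run} to one of exactly two
#' \code{condition} values. Row order is preserved; missing or negative
#' counts are rejected with the offending row and column named.
#'
#' @param countsFile,designFile paths to the two tables.
#' @return a validated \linkS4class{SpectralCounts}.
#' @seealso [writeSpectralCounts()] for the inverse.
#' @export
readSpectralCounts <- function(countsFile, designFile) {
    tab <- .readTable(countsFile)
    des <- .readTable(designFile)
    if (!all(c("run", "condition") %in% colnames(des)))
        stop("design file needs 'run' and 'condition' columns")
    if (!"protein_id" %in% colnames(tab))
        stop("counts file needs a 'protein_id' column")
    meta <- intersect(c("protein_id", "description", "is_contaminant",
                        "is_decoy"), colnames(tab))
    runCols <- setdiff(colnames(tab), meta)
    if (!all(runCols %in% des$run))
        stop(sprintf("run column(s) missing from design: %s",
                     paste(setdiff(runCols, des$run), collapse = ", ")))
    if (!all(des$run %in% runCols))
        stop(sprintf("design run(s) absent from counts file: %s",
                     paste(setdiff(des$run, runCols), collapse = ", ")))
    cnt <- as.matrix(tab[runCols])
    if (!is.numeric(cnt))
        stop("non-numeric count column(s) found")
    bad <- which(is.na(cnt) | cnt < 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("missing or negative count at protein '%s', run '%s'",
                     tab$protein_id[bad[1L, 1L]], runCols[bad[1L, 2L]]))
    rownames(cnt) <- tab$protein_id
    # design row order defines the condition level order
    des <- des[match(runCols, des$run), ]
    SpectralCounts(cnt, condition = des$condition,
        description = if ("description" %in% meta) tab$description,
        isContaminant = if ("is_contaminant" %in% meta)
            as.logical(tab$is_contaminant),
        isDecoy = if ("is_decoy" %in% meta) as.logical(tab$is_decoy))
}

#' Write a SpectralCounts object as counts + design tables
#'
#' Inverse of [readSpectralCounts()]: `readSpectralCounts` on the written
#' files reproduces the object.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param countsFile,designFile output paths (TSV unless the extension is
#'   \code{.csv}).
#' @return invisibly, \code{x}.
#' @export
writeSpectralCounts <- function(x, countsFile, designFile) {
    rd <- SummarizedExperiment::rowData(x)
    tab <- data.frame(protein_id = rownames(x), stringsAsFactors = FALSE)
    if (!is.null(rd$description)) tab$description <- rd$description
    if (!is.null(rd$isContaminant)) tab$is_contaminant <- rd$isContaminant
    if (!is.null(rd$isDecoy)) tab$is_decoy <- rd$isDecoy
    tab <- cbind(tab, as.data.frame(scCounts(x), check.names = FALSE))
    des <- data.frame(run = colnames(x),
                      condition = as.character(runConditions(x)))
    .writeTab <- function(d, path) {
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
        utils::write.table(d, path, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    .writeTab(tab, countsFile)
    .writeTab(des, designFile)
    invisible(x)
}

#' Remove contaminant and decoy identifications
#'
#' Drops proteins flagged as keratin-family contaminants or reverse-database
#' decoys before quantification. Flags come from the \code{isContaminant} /
#' \code{isDecoy} rowData columns when present; otherwise they are derived
#' from a case-insensitive \code{descriptionPattern} match on the protein
#' description and a \code{decoyPattern} match on the accession. A protein
#' matching both categories is counted as a contaminant, so the removed
#' categories partition the input exactly:
#' kept + contaminants + decoys = input.
#'
#' @param x a \linkS4class{SpectralCounts}.
#' @param descriptionPattern regex flagging contaminants in the description
#'   (default \code{"keratin"}, case-insensitive).
#' @param decoyPattern regex flagging decoy accessions (default
#'   \code{"^rev_"}, case-insensitive, covering \code{rev_}/\code{REV_}).
#' @return the filtered \linkS4class{SpectralCounts}; the removal summary is
#'   stored in its metadata and retrievable with [filterSummary()].
#' @export
filterIdentifications <- function(x, descriptionPattern = "keratin",
                                  decoyPattern = "^rev_") {
    rd <- SummarizedExperiment::rowData(x)
    contam <- if (!is.null(rd$isContaminant)) rd$isContaminant %in% TRUE
        else if (!is.null(rd$description))
            grepl(descriptionPattern, rd$description, ignore.case = TRUE)
        else rep(FALSE, nrow(x))
    decoy <- if (!is.null(rd$isDecoy)) rd$isDecoy %in% TRUE
        else grepl(decoyPattern, rownames(x), ignore.case = TRUE)
    decoy <- decoy & !contam        # contaminant takes precedence
    keep <- !contam & !decoy
    out <- x[keep, ]
    if (!any(keep))
        warning("all proteins were removed by identification filtering")
    S4Vectors::metadata(out)$filterSummary <- list(
        nInput = nrow(x), nContaminant = sum(contam), nDecoy = sum(decoy),
        nKept = sum(keep))
    out
}

#' @param x a \linkS4class{SpectralCounts} returned by
#'   [filterIdentifications()].
#' @return \code{filterSummary}: list with \code{nInput},
#'   \code{nContaminant}, \code{nDecoy}, \code{nKept}.
#' @rdname filterIdentifications
#' @export
setMethod("filterSummary", "SpectralCounts", function(x)
    S4Vectors::metadata(x)$filterSummary)

#' Normalize runs to the grand-mean run total
#'
#' Scales every run (column) by grand-mean total / run total, so that all
#' run totals become equal while within-run proportions are preserved.
#' Normalized counts are fractional and are not re-rounded. The operation is
#' idempotent.
#'
#' @param x a \linkS4class{SpectralCounts}; every run must have a positive
#'   total.
#' @return \code{x} with scaled counts, per-run \code{sizeFactor}s in
#'   colData, and \code{normalized = TRUE} in metadata.
#' @export
normalizeCounts <- function(x) {
    cnt <- scCounts(x)
    totals <- colSums(cnt)
    if (any(totals == 0))
        stop(sprintf("run(s) with zero total count: %s",
                     paste(colnames(x)[totals == 0], collapse = ", ")))
    fac <- mean(totals) / totals
    SummarizedExperiment::assay(x, "counts") <- sweep(cnt, 2L, fac, `*`)
    SummarizedExperiment::colData(x)$sizeFactor <- fac
    S4Vectors::metadata(x)$normalized <- TRUE
    x
}
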