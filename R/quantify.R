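## Window counting, RPKM, coverage filtering and log2 transformation.

#' Count retained fragments per window
#'
#' Each fragment is assigned to exactly one window by the leftmost aligned
#' base of its leftmost mate, so counts are conserved (fragments are never
#' double-counted and never extended across windows).
#'
#' @param retained A \linkS4class{RetainedReadSet}.
#' @param grid A \linkS4class{WindowGrid}.
#' @return Integer vector of per-window counts summing to the number of
#'   fragments.
#' @export
countFragments <- function(retained, grid) {
    pos <- retainedFragments(retained)$pos
    if (length(pos) && any(pos > grid@genomeLength))
        stop("fragment position beyond genome length")
    idx <- (pos - 1L) %/% grid@windowSize + 1L
    as.integer(tabulate(idx, nbins = nWindows(grid)))
}

#' Reads per kilobase per million mapped fragments
#'
#' \code{count / ((windowLength/1000) * (total/1e6))}.  The denominator is
#' the sample's total retained mitochondrial fragments (the analysis
#' universe after triage); pass an externally derived total to reproduce a
#' genome-wide normalisation instead.
#'
#' @param count Fragment count(s) in the window.
#' @param windowLength Window length in bp.
#' @param total Total mapped fragments for the sample (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, windowLength, total) {
    if (any(total <= 0)) stop("total mapped fragments must be > 0")
    if (any(windowLength <= 0)) stop("window length must be > 0")
    count / ((windowLength / 1000) * (total / 1e6))
}

#' Coverage filter: which windows are analyzed
#'
#' A window is analyzed only if its fragment count exceeds \code{minCount}
#' (strictly) in the configured scope: in \emph{every} sample (default,
#' which makes a single not-determined flag per window well defined) or in
#' the \emph{total} across samples.
#'
#' @param counts Integer matrix, windows x samples.
#' @param minCount Strict lower bound (default 10: a window needs > 10
#'   fragments).
#' @param scope "all" (default) or "total".
#' @return Logical analyzed mask per window.
#' @export
filterWindows <- function(counts, minCount = 10L, scope = c("all", "total")) {
    scope <- match.arg(scope)
    counts <- as.matrix(counts)
    if (scope == "all") apply(counts > minCount, 1L, all)
    else rowSums(counts) > minCount
}

#' log2-transform RPKM values on analyzed windows
#'
#' @param rpkmMat Numeric matrix, windows x samples.
#' @param mask Logical analyzed mask; not-determined windows are set to
#'   \code{NA}.
#' @return Matrix of log2 RPKM (NA where not analyzed).
#' @export
log2Transform <- function(rpkmMat, mask) {
    rpkmMat <- as.matrix(rpkmMat)
    stopifnot(length(mask) == nrow(rpkmMat))
    if (any(rpkmMat[mask, , drop = FALSE] <= 0))
        stop("non-positive RPKM in an analyzed window")
    out <- matrix(NA_real_, nrow(rpkmMat), ncol(rpkmMat),
                  dimnames = dimnames(rpkmMat))
    out[mask, ] <- log2(rpkmMat[mask, , drop = FALSE])
    out
}

#' Assemble a WindowExperiment from per-sample counts
#'
#' Computes RPKM (per-sample totals as denominator), applies the coverage
#' filter and the log2 transform, and packages everything as a
#' \linkS4class{WindowExperiment} with windows as rows and samples as
#' columns.
#'
#' @param counts Integer matrix, windows x samples (column names are sample
#'   ids).
#' @param grid A \code{WindowGrid}.
#' @param samples \code{data.frame} with one row per sample (e.g. columns
#'   \code{individual}, \code{tissue}).
#' @param geneLabels Optional per-window gene labels.
#' @param minCount,scope Passed to \code{\link{filterWindows}}.
#' @param totals Optional externally supplied per-sample totals for the
#'   RPKM denominator; defaults to column sums.
#' @return A \code{WindowExperiment}.
#' @export
buildWindowExperiment <- function(counts, grid, samples,
                                  geneLabels = NULL, minCount = 10L,
                                  scope = c("all", "total"), totals = NULL) {
    scope <- match.arg(scope)
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == nWindows(grid), nrow(samples) == ncol(counts))
    if (is.null(totals)) totals <- colSums(counts)
    rp <- counts / outer(IRanges::width(windowRanges(grid)) / 1000,
                         totals / 1e6)
    mask <- filterWindows(counts, minCount = minCount, scope = scope)
    lg <- log2Transform(rp, mask)
    s <- windowStarts(grid)
    rd <- DataFrame(start = s, stop = s + grid@windowSize - 1L,
                    gene = if (is.null(geneLabels)) NA_character_
                           else geneLabels,
                    analyzed = mask)
    se <- SummarizedExperiment(
        assays = list(counts = counts, rpkm = rp, log2rpkm = lg),
        rowData = rd, colData = DataFrame(samples))
    rownames(se) <- windowLabels(grid)
    we <- new("WindowExperiment", se)
    metadata(we)$grid <- grid
    metadata(we)$totals <- totals
    we
}

#' @rdname buildWindowExperiment
#' @param we A \code{WindowExperiment}.
#' @return \code{analyzedWindows}: logical mask of analyzed (non-ND)
#'   windows.
#' @export
analyzedWindows <- function(we) rowData(we)$analyzed

#' Write / read a WindowExperiment assay as TSV
#'
#' Windows as rows ("start stop gene ND" plus one column per sample,
#' mirroring the package's table exports); \code{readWindowMatrixTsv}
#' round-trips the file.
#'
#' @param we A \code{WindowExperiment}.
#' @param path Output TSV.
#' @param assayName Which assay to write.
#' @export
writeWindowMatrixTsv <- function(we, path, assayName = "rpkm") {
    rd <- rowData(we)
    m <- assay(we, assayName)
    df <- data.frame(start = rd$start, stop = rd$stop, gene = rd$gene,
                     ND = ifelse(rd$analyzed, "", "ND"),
                     m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeWindowMatrixTsv
#' @export
readWindowMatrixTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    df$ND[is.na(df$ND)] <- ""
    m <- as.matrix(df[, -(1:4), drop = FALSE])
    list(start = df$start, stop = df$stop, gene = df$gene,
         analyzed = df$ND != "ND", matrix = m)
}
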