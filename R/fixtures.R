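## Packaged transcriptions of the two published per-window result tables
## (five cortical regions vs cerebellum, paired t; total cortex vs
## cerebellum, mixed model) and the counting operations that summarise
## them.

.fixturePath <- function(f)
    system.file("extdata", f, package = "MitoMeDIP", mustWork = TRUE)

#' Load the packaged result-table transcriptions
#'
#' Parses the two per-window tables (166 rows of 100 bp windows labelled to
#' 16600), validating shape, window agreement, that printed p values lie in
#' (0, 0.05) (only nominally significant values are printed) and that the
#' not-determined (ND) pattern agrees between the tables.  As published the
#' ND patterns differ at two windows (3101-3200 and 4101-4200 are ND in the
#' five-region table but merely non-significant in the total-cortex table);
#' the discrepancy is reported via a warning, or an error with
#' \code{strict = TRUE}.  The multiple-testing count
#' (\code{nAnalyzed}) is the five-region table's non-ND window count, the
#' value consistent with the published Bonferroni threshold.
#'
#' @param strict Error (rather than warn) on ND-pattern disagreement.
#' @return List with \code{table2} (wide five-region table), \code{table3}
#'   (total-cortex table), \code{long2} (table2 in long result form, one
#'   row per window x comparison), \code{comparisons}, \code{grid},
#'   \code{nAnalyzed} and \code{ndMismatch} (starts of discrepant windows).
#' @export
loadFixtureTables <- function(strict = FALSE) {
    t2 <- read.delim(.fixturePath("table2_cortical_regions_vs_cerebellum.tsv"),
                     colClasses = "character")
    t3 <- read.delim(.fixturePath("table3_total_cortex_vs_cerebellum.tsv"),
                     colClasses = "character")
    t2$start <- as.integer(t2$start); t2$stop <- as.integer(t2$stop)
    t3$start <- as.integer(t3$start); t3$stop <- as.integer(t3$stop)
    t2$bold <- as.logical(t2$bold); t3$bold <- as.logical(t3$bold)
    if (nrow(t2) != 166L || nrow(t3) != 166L)
        stop("fixture tables must have 166 windows")
    if (!identical(t2$start, t3$start) || !identical(t2$stop, t3$stop) ||
        !identical(t2$gene, t3$gene))
        stop("window sets differ between the fixture tables")
    comps <- c("BA8", "BA9", "BA10", "ECX", "STG")
    pcols <- paste0(comps, "_p")
    isP <- function(x) !(x %in% c("-", "ND"))
    for (cc in pcols) {
        v <- suppressWarnings(as.numeric(t2[[cc]][isP(t2[[cc]])]))
        if (anyNA(v) || any(v <= 0) || any(v >= 0.05))
            stop("printed p values must lie in (0, 0.05): ", cc)
    }
    v3 <- suppressWarnings(as.numeric(t3$p[isP(t3$p)]))
    if (anyNA(v3) || any(v3 <= 0) || any(v3 >= 0.05))
        stop("printed p values must lie in (0, 0.05): total-cortex table")
    nd2 <- t2$BA8_p == "ND"
    if (!all(apply(as.matrix(t2[pcols]) == "ND", 1L, function(r)
        all(r) || !any(r))))
        stop("ND must apply to all comparisons of a window")
    nd3 <- t3$p == "ND"
    mism <- t2$start[nd2 != nd3]
    if (length(mism)) {
        msg <- paste("ND patterns disagree between tables at window(s)",
                     paste(mism, collapse = ", "))
        if (strict) stop(msg) else warning(msg)
    }
    grid <- tileWindows(16600L, 100L)

    long2 <- do.call(rbind, lapply(comps, function(cc) {
        p <- t2[[paste0(cc, "_p")]]
        d <- t2[[paste0(cc, "_delta")]]
        data.frame(start = t2$start, stop = t2$stop, gene = t2$gene,
                   comparison = paste0(cc, "-vs-CER"),
                   p = suppressWarnings(as.numeric(ifelse(isP(p), p, NA))),
                   delta = suppressWarnings(as.numeric(
                       ifelse(isP(d), d, NA))),
                   analyzed = p != "ND", stringsAsFactors = FALSE)
    }))
    list(table2 = t2, table3 = t3, long2 = long2,
         comparisons = paste0(comps, "-vs-CER"), grid = grid,
         nAnalyzed = sum(!nd2), ndMismatch = mism)
}

#' Recompute every published summary count from the fixture tables
#'
#' From the packaged table transcriptions alone (no raw data), recomputes:
#' the number of nominally significant entries in the five-region analysis
#' and of nominally significant windows in the total-cortex analysis; the
#' Bonferroni threshold as alpha over the number of analyzed windows and
#' the windows passing it, with their longest adjacent run; and the windows
#' nominally significant across all three prefrontal regions, their
#' hypo/hyper split and longest adjacent run.
#'
#' @param fixtures Output of \code{\link{loadFixtureTables}} (loaded fresh
#'   when \code{NULL}).
#' @param alpha Nominal significance level (default 0.05).
#' @return Named list of counts and thresholds.
#' @export
reproducePublishedCounts <- function(fixtures = NULL, alpha = 0.05) {
    fx <- if (is.null(fixtures))
        suppressWarnings(loadFixtureTables()) else fixtures
    long2 <- fx$long2
    grid <- fx$grid
    prefrontal <- paste0(c("BA8", "BA9", "BA10"), "-vs-CER")

    nominalEntries <- countNominal(long2, alpha = alpha, level = "entries")
    cons <- conservedWindows(long2, prefrontal, alpha = alpha)
    thr <- bonferroniThreshold(fx$nAnalyzed, alpha = alpha)

    t3 <- fx$table3
    p3 <- suppressWarnings(as.numeric(ifelse(t3$p %in% c("-", "ND"), NA,
                                             t3$p)))
    res3 <- data.frame(start = t3$start, stop = t3$stop, gene = t3$gene,
                       comparison = "CTX-vs-CER", p = p3,
                       analyzed = t3$p != "ND", stringsAsFactors = FALSE)
    nominalWindows3 <- countNominal(res3, alpha = alpha, level = "windows")
    bonf <- res3$start[!is.na(res3$p) & res3$p < thr]

    list(nominal_entries_five_region = nominalEntries,
         conserved_prefrontal_windows = nrow(cons),
         conserved_hypomethylated = sum(cons$direction == "hypo"),
         conserved_hypermethylated = sum(cons$direction == "hyper"),
         conserved_longest_adjacent_run = longestAdjacentRun(cons$start,
                                                             grid),
         nominal_windows_total_cortex = nominalWindows3,
         analyzed_windows = fx$nAnalyzed,
         bonferroni_threshold = thr,
         bonferroni_significant_windows = length(bonf),
         bonferroni_longest_adjacent_run = longestAdjacentRun(bonf, grid))
}

#' The packaged window gene-label annotation
#'
#' Interval annotation derived from the per-window gene labels of the
#' packaged tables (see \code{\link{annotationFromWindowLabels}}); it
#' reproduces those labels exactly under \code{\link{annotateWindows}} but
#' is synthetic at sub-window resolution.
#'
#' @return A \linkS4class{MitoAnnotation}.
#' @export
packagedMitoAnnotation <- function()
    readMitoAnnotation(.fixturePath("mito_gene_intervals.synthetic.tsv"))
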