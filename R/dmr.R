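## Per-window differential-methylation statistics, multiple-testing control,
## conserved-DMR logic and the counting operations used on result tables.
##
## Results are exchanged as long-format data.frames with columns
## start, stop, gene, comparison, p, delta, analyzed (one row per
## window x comparison); delta is mean(cortex) - mean(cerebellum) on the
## analysis scale, so delta < 0 means hypomethylated relative to cerebellum.

#' Two-tailed paired t test for one window
#'
#' Standard paired t on the differences \code{d = x - y} (matched by
#' individual), \code{df = n - 1}.  Zero-variance differences are not
#' analyzable and are returned with a distinct code rather than a fabricated
#' p of 0 or 1.
#'
#' @param x,y Per-individual values in the two conditions (equal length
#'   >= 2, matched order).
#' @return List with \code{p}, \code{delta} (= mean(d)) and \code{code}
#'   ("ok" or "zero_variance", in which case \code{p} is \code{NA}).
#' @export
pairedTWindow <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must be matched by individual")
    if (length(x) < 2L) stop("paired t needs at least 2 pairs")
    d <- x - y
    if (sd(d) == 0)
        return(list(p = NA_real_, delta = mean(d), code = "zero_variance"))
    ht <- t.test(x, y, paired = TRUE, alternative = "two.sided")
    list(p = unname(ht$p.value), delta = mean(d), code = "ok")
}

#' Mixed-effects model for one window: tissue effect, total cortex vs
#' cerebellum
#'
#' Default model: \code{value ~ tissue + (1 | individual)}, p for the
#' tissue effect by likelihood-ratio test against the model without tissue
#' (ML fits).  A "transposed" mode instead fits
#' \code{value ~ individual + (1 | region)} and reports the
#' model-comparison p for adding tissue; only the default directly tests
#' cortex vs cerebellum.  Wald z p available by flag.
#'
#' @param data \code{data.frame} with columns \code{value}, \code{tissue}
#'   (two levels, e.g. cortex/cerebellum), \code{individual}, \code{region}.
#' @param mode "default" or "transposed".
#' @param test "LRT" (default) or "Wald".
#' @return List with \code{p} and \code{code} ("ok" or "singular", flagged
#'   when a random-effect variance collapses to the boundary).
#' @export
mixedModelWindow <- function(data, mode = c("default", "transposed"),
                             test = c("LRT", "Wald")) {
    mode <- match.arg(mode)
    test <- match.arg(test)
    stopifnot(all(c("value", "tissue", "individual") %in% names(data)))
    if (length(unique(data$tissue)) != 2L)
        stop("exactly two tissue levels required")
    if (length(unique(data$individual)) < 2L)
        stop("at least two individuals required")
    data$tissue <- factor(data$tissue)
    if (sd(data$value) == 0)
        return(list(p = NA_real_, code = "singular"))
    ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
    if (mode == "default") {
        full <- suppressWarnings(suppressMessages(
            lmer(value ~ tissue + (1 | individual), data = data,
                 REML = FALSE, control = ctl)))
        null <- suppressWarnings(suppressMessages(
            lmer(value ~ 1 + (1 | individual), data = data,
                 REML = FALSE, control = ctl)))
    } else {
        stopifnot("region" %in% names(data))
        full <- suppressWarnings(suppressMessages(
            lmer(value ~ individual + tissue + (1 | region), data = data,
                 REML = FALSE, control = ctl)))
        null <- suppressWarnings(suppressMessages(
            lmer(value ~ individual + (1 | region), data = data,
                 REML = FALSE, control = ctl)))
    }
    code <- if (isSingular(full, tol = 1e-5)) "singular" else "ok"
    if (test == "LRT") {
        a <- suppressWarnings(suppressMessages(anova(null, full)))
        p <- a[["Pr(>Chisq)"]][2]
    } else {
        cf <- summary(full)$coefficients
        row <- grep("^tissue", rownames(cf))[1]
        z <- cf[row, "t value"]
        p <- 2 * stats::pnorm(-abs(z))
    }
    if (!is.finite(p)) {
        p <- NA_real_
        code <- "singular"
    }
    list(p = unname(p), code = code)
}

#' Bonferroni threshold over the analyzed windows
#'
#' @param nTests Number of tests (>= 1), conventionally the number of
#'   analyzed (non-ND) windows.
#' @param alpha Family-wise level (default 0.05).
#' @return \code{alpha / nTests}.
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
    if (nTests < 1L) stop("nTests must be >= 1")
    alpha / nTests
}

#' Count nominally significant results
#'
#' @param results Long result table (columns \code{start}, \code{comparison},
#'   \code{p}, \code{analyzed}).
#' @param alpha Nominal level (default 0.05).
#' @param level "entries" counts (window x comparison) pairs with p < alpha
#'   (what the five-region analysis tabulates); "windows" counts distinct
#'   windows.
#' @return Integer count.
#' @export
countNominal <- function(results, alpha = 0.05,
                         level = c("entries", "windows")) {
    level <- match.arg(level)
    sig <- !is.na(results$p) & results$analyzed & results$p < alpha
    if (level == "entries") sum(sig)
    else length(unique(results$start[sig]))
}

#' Windows significant across every comparison of a subset
#'
#' @param results Long result table (needs \code{delta} as well).
#' @param comparisons Character subset of comparisons that must all be
#'   nominally significant.
#' @param alpha Nominal level.
#' @return \code{data.frame} with \code{start} and \code{direction}
#'   ("hyper" if delta > 0 in all comparisons, "hypo" if < 0 in all,
#'   "mixed" otherwise).
#' @export
conservedWindows <- function(results, comparisons, alpha = 0.05) {
    r <- results[results$comparison %in% comparisons, , drop = FALSE]
    sig <- !is.na(r$p) & r$analyzed & r$p < alpha
    nsig <- tapply(sig, r$start, sum)
    hits <- as.integer(names(nsig)[nsig == length(comparisons)])
    hits <- sort(hits)
    dir <- vapply(hits, function(s) {
        d <- r$delta[r$start == s]
        if (all(d > 0)) "hyper" else if (all(d < 0)) "hypo" else "mixed"
    }, "")
    data.frame(start = hits, direction = dir, stringsAsFactors = FALSE)
}

#' Longest run of adjacent windows within a set
#'
#' @param starts Window start coordinates (drawn from the grid).
#' @param grid The \code{WindowGrid} they come from.
#' @return Length of the longest maximal run of consecutive grid windows
#'   contained in the set (0 for an empty set).
#' @export
longestAdjacentRun <- function(starts, grid) {
    if (length(starts) == 0L) return(0L)
    idx <- match(starts, windowStarts(grid))
    if (anyNA(idx)) stop("window start not on the grid")
    idx <- sort(idx)
    best <- 1L
    cur <- 1L
    for (d in diff(idx)) {
        cur <- if (d == 1L) cur + 1L else 1L
        best <- max(best, cur)
    }
    best
}

#' Direction concordance between two delta profiles
#'
#' Percentage of windows whose methylation-difference sign agrees between
#' two comparisons; windows with a zero delta in either profile are
#' excluded from numerator and denominator.
#'
#' @param deltaA,deltaB Equal-length numeric vectors over the analyzed
#'   windows.
#' @return Percentage in [0, 100], or \code{NA} (with a warning) when no
#'   window has two nonzero deltas.
#' @export
directionConcordance <- function(deltaA, deltaB) {
    stopifnot(length(deltaA) == length(deltaB))
    use <- deltaA != 0 & deltaB != 0 & !is.na(deltaA) & !is.na(deltaB)
    if (!any(use)) {
        warning("no windows with two nonzero deltas; concordance undefined")
        return(NA_real_)
    }
    100 * sum(sign(deltaA[use]) == sign(deltaB[use])) / sum(use)
}

#' Per-window paired t tests between a tissue and cerebellum
#'
#' Runs \code{\link{pairedTWindow}} on log2 RPKM across every analyzed
#' window of a \code{WindowExperiment}, matching samples by individual.
#'
#' @param we A \code{WindowExperiment} whose \code{colData} has
#'   \code{individual} and \code{tissue}.
#' @param tissueA Comparison tissue (e.g. "BA8").
#' @param tissueB Baseline tissue (default "CER").
#' @param assayName Assay tested (default "log2rpkm").
#' @return Long result table (one row per window) with the comparison
#'   labelled "tissueA-vs-tissueB"; ND windows carry \code{NA} p and delta.
#' @export
dmrPairedTest <- function(we, tissueA, tissueB = "CER",
                          assayName = "log2rpkm") {
    cd <- colData(we)
    ia <- which(cd$tissue == tissueA)
    ib <- which(cd$tissue == tissueB)
    common <- intersect(cd$individual[ia], cd$individual[ib])
    if (length(common) < 2L) stop("need >= 2 matched individuals")
    ia <- ia[match(common, cd$individual[ia])]
    ib <- ib[match(common, cd$individual[ib])]
    m <- assay(we, assayName)
    rd <- rowData(we)
    out <- data.frame(start = rd$start, stop = rd$stop, gene = rd$gene,
                      comparison = paste0(tissueA, "-vs-", tissueB),
                      p = NA_real_, delta = NA_real_, code = "ND",
                      analyzed = rd$analyzed, stringsAsFactors = FALSE)
    for (w in which(rd$analyzed)) {
        r <- pairedTWindow(m[w, ia], m[w, ib])
        out$p[w] <- r$p; out$delta[w] <- r$delta; out$code[w] <- r$code
    }
    out
}

#' Per-window mixed-model tests, total cortex vs cerebellum
#'
#' @param we A \code{WindowExperiment}; \code{colData} needs
#'   \code{individual} and \code{tissue}.
#' @param cortexTissues Tissues pooled as "cortex".
#' @param cerebellum Cerebellum tissue label.
#' @param assayName Assay tested.
#' @param mode,test Passed to \code{\link{mixedModelWindow}}.
#' @return Long result table with comparison "CTX-vs-CER"; delta is the
#'   cortex minus cerebellum mean.
#' @export
dmrMixedTest <- function(we, cortexTissues = c("BA8", "BA9", "BA10", "ECX",
                                               "STG"),
                         cerebellum = "CER", assayName = "log2rpkm",
                         mode = "default", test = "LRT") {
    cd <- colData(we)
    use <- cd$tissue %in% c(cortexTissues, cerebellum)
    tissue <- ifelse(cd$tissue[use] %in% cortexTissues, "cortex",
                     "cerebellum")
    m <- assay(we, assayName)[, use, drop = FALSE]
    rd <- rowData(we)
    out <- data.frame(start = rd$start, stop = rd$stop, gene = rd$gene,
                      comparison = "CTX-vs-CER", p = NA_real_,
                      delta = NA_real_, code = "ND",
                      analyzed = rd$analyzed, stringsAsFactors = FALSE)
    for (w in which(rd$analyzed)) {
        df <- data.frame(value = m[w, ], tissue = tissue,
                         individual = cd$individual[use],
                         region = cd$tissue[use])
        r <- mixedModelWindow(df, mode = mode, test = test)
        out$p[w] <- r$p
        out$delta[w] <- mean(df$value[tissue == "cortex"]) -
            mean(df$value[tissue == "cerebellum"])
        out$code[w] <- r$code
    }
    out
}

#' Export a long result table as a wide TSV mirroring the package's result
#' tables, or significant windows as BED
#'
#' @param results Long result table.
#' @param path Output file.
#' @param format "tsv" (wide; p and delta per comparison, ND column) or
#'   "bed" (significant windows, 0-based half-open).
#' @param alpha Significance threshold used for BED export.
#' @export
writeDmrResults <- function(results, path, format = c("tsv", "bed"),
                            alpha = 0.05) {
    format <- match.arg(format)
    if (format == "tsv") {
        comps <- unique(results$comparison)
        base <- unique(results[c("start", "stop", "gene")])
        base <- base[order(base$start), , drop = FALSE]
        base$ND <- ifelse(results$analyzed[match(base$start, results$start)],
                          "", "ND")
        for (cc in comps) {
            r <- results[results$comparison == cc, , drop = FALSE]
            i <- match(base$start, r$start)
            base[[paste0(cc, "_p")]] <- r$p[i]
            base[[paste0(cc, "_delta")]] <- r$delta[i]
        }
        write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        sig <- results[!is.na(results$p) & results$p < alpha, , drop = FALSE]
        bed <- data.frame(chrom = "chrM", start = sig$start - 1L,
                          end = sig$stop, name = sig$comparison,
                          score = round(-10 * log10(pmax(sig$p, 1e-300))))
        write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(path)
}
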