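## Reference-genome handling, nuclear-only reference construction, window
## tiling and window gene annotation.

.MITO_ALIASES <- c("chrm", "mt", "chrmt")

#' Construct a ReferenceGenome
#'
#' @param sequences Named \code{DNAStringSet} (or named character vector).
#' @param mitoName Name of the mitochondrial record.  When \code{NULL}, a
#'   record named "chrM", "MT" or "chrMT" (case-insensitively) is designated
#'   automatically; an explicit name always wins.
#' @param circular Circularity flag for the mitochondrial record.  Recorded;
#'   alignment and windowing treat the sequence as linear by default.
#' @return A \linkS4class{ReferenceGenome}.
#' @export
referenceGenome <- function(sequences, mitoName = NULL, circular = TRUE) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- DNAStringSet(toupper(sequences))
    if (is.null(mitoName)) {
        hit <- which(tolower(names(sequences)) %in% .MITO_ALIASES)
        mitoName <- if (length(hit)) names(sequences)[hit[1]] else NA_character_
    }
    new("ReferenceGenome", sequences = sequences, mitoName = mitoName,
        circular = circular)
}

#' Load a reference genome from FASTA
#'
#' Records are upper-cased on load.  The mitochondrial record is
#' auto-detected by name ("chrM"/"MT"/"chrMT", case-insensitive) unless
#' \code{mitoName} is given.
#'
#' @param path Path to a FASTA file.
#' @inheritParams referenceGenome
#' @return A \linkS4class{ReferenceGenome}.
#' @export
loadReference <- function(path, mitoName = NULL, circular = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    seqs <- tryCatch(readDNAStringSet(path),
                     error = function(e) stop("malformed FASTA: ",
                                              conditionMessage(e)))
    if (length(seqs) == 0L) stop("empty FASTA: ", path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs))) stop("duplicate record names in ", path)
    seqs <- DNAStringSet(toupper(as.character(seqs)))
    referenceGenome(seqs, mitoName = mitoName, circular = circular)
}

#' @describeIn loadReference Write a reference to FASTA.
#' @param ref A \code{ReferenceGenome}.
#' @export
writeReference <- function(ref, path) {
    writeXStringSet(refSequences(ref), path)
    invisible(path)
}

#' Accessors for ReferenceGenome
#'
#' @param x A \code{ReferenceGenome}.
#' @return \code{refSequences}: the \code{DNAStringSet}; \code{mitoName}: the
#'   mitochondrial record name (\code{NA} if unset); \code{mitoSequence}: the
#'   mitochondrial record.
#' @export
refSequences <- function(x) x@sequences

#' @rdname refSequences
#' @export
mitoName <- function(x) x@mitoName

#' @rdname refSequences
#' @export
mitoSequence <- function(x) {
    if (is.na(x@mitoName)) stop("no mitochondrial record designated")
    x@sequences[[x@mitoName]]
}

setMethod("show", "ReferenceGenome", function(object) {
    cat("ReferenceGenome with", length(object@sequences), "record(s)\n")
    w <- Biostrings::width(object@sequences)
    for (i in seq_along(w))
        cat(sprintf("  %s: %d bp%s\n", names(object@sequences)[i], w[i],
            if (!is.na(object@mitoName) &&
                names(object@sequences)[i] == object@mitoName)
                " [mitochondrial]" else ""))
})

#' Drop the mitochondrial record from a reference
#'
#' Builds the nuclear-only reference used by the second triage pass: all
#' records except the designated mitochondrial one, byte-identical, with no
#' mitochondrial designation.
#'
#' @param ref A \code{ReferenceGenome} with \code{mitoName} set.
#' @return A \code{ReferenceGenome} without the mitochondrial record.
#' @export
buildNuclearOnly <- function(ref) {
    if (is.na(mitoName(ref)))
        stop("reference has no designated mitochondrial record")
    keep <- names(refSequences(ref)) != mitoName(ref)
    new("ReferenceGenome", sequences = refSequences(ref)[keep],
        mitoName = NA_character_, circular = FALSE)
}

#' Tile a genome into non-overlapping windows
#'
#' Produces \code{ceiling(genomeLength / windowSize)} contiguous windows in
#' 1-based inclusive coordinates; the last window is truncated at
#' \code{genomeLength}.  Window \emph{labels} elsewhere in the package use
#' the nominal 100 bp bounds (so a 16,569 bp mitochondrial genome still
#' yields a 166-window grid labelled to 16600); truncation applies only to
#' counting.
#'
#' @param genomeLength Sequence length in bases (>= 1).
#' @param windowSize Window width in bases (default 100).
#' @return A \linkS4class{WindowGrid}.
#' @export
tileWindows <- function(genomeLength, windowSize = 100L) {
    genomeLength <- as.integer(genomeLength)
    windowSize <- as.integer(windowSize)
    if (is.na(genomeLength) || genomeLength < 1L)
        stop("genomeLength must be >= 1")
    if (is.na(windowSize) || windowSize < 1L)
        stop("windowSize must be >= 1")
    s <- seq.int(1L, genomeLength, by = windowSize)
    e <- pmin(s + windowSize - 1L, genomeLength)
    new("WindowGrid", ranges = IRanges(s, e), windowSize = windowSize,
        genomeLength = genomeLength)
}

#' Accessors for WindowGrid
#' @param x A \code{WindowGrid}.
#' @export
windowRanges <- function(x) x@ranges

#' @rdname windowRanges
#' @export
nWindows <- function(x) length(x@ranges)

#' @rdname windowRanges
#' @export
windowStarts <- function(x) IRanges::start(x@ranges)

#' @rdname windowRanges
#' @details \code{windowLabels} returns "start-stop" labels with nominal
#'   (untruncated) bounds.
#' @export
windowLabels <- function(x) {
    s <- windowStarts(x)
    paste0(s, "-", s + x@windowSize - 1L)
}

setMethod("show", "WindowGrid", function(object) {
    cat(sprintf("WindowGrid: %d windows of %d bp over %d bp\n",
                length(object@ranges), object@windowSize,
                object@genomeLength))
})

#' Read a mitochondrial gene annotation
#'
#' Accepts a 4-column TSV (\code{name}, \code{start}, \code{stop},
#' \code{strand}; 1-based inclusive, with a header) or BED (0-based
#' half-open, converted on load).
#'
#' @param path Annotation file.
#' @param format "tsv" or "bed".
#' @param controlRegion Label for windows overlapping no gene.
#' @return A \linkS4class{MitoAnnotation}.
#' @export
readMitoAnnotation <- function(path, format = c("tsv", "bed"),
                               controlRegion = "D-Loop") {
    format <- match.arg(format)
    if (format == "tsv") {
        g <- read.delim(path, stringsAsFactors = FALSE)
        if (!all(c("name", "start", "stop", "strand") %in% names(g)))
            stop("TSV annotation needs columns name, start, stop, strand")
    } else {
        b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
        g <- data.frame(name = b[[4]], start = b[[2]] + 1L, stop = b[[3]],
                        strand = if (ncol(b) >= 6) b[[6]] else "*",
                        stringsAsFactors = FALSE)
    }
    g <- g[order(g$start, g$stop), , drop = FALSE]
    new("MitoAnnotation", genes = g, controlRegion = controlRegion)
}

#' @rdname readMitoAnnotation
#' @param ann A \code{MitoAnnotation}.
#' @export
annotationGenes <- function(ann) ann@genes

#' Label windows with overlapping genes
#'
#' Each window is labelled with the "/"-joined names of all genes
#' overlapping it, in genomic order; windows overlapping no gene receive the
#' annotation's control-region label.  Labelling is deterministic and
#' order-stable.
#'
#' @param grid A \code{WindowGrid}.
#' @param ann A \code{MitoAnnotation} whose coordinates lie within the grid.
#' @return Character vector of per-window labels.
#' @export
annotateWindows <- function(grid, ann) {
    g <- annotationGenes(ann)
    lab <- rep(ann@controlRegion, nWindows(grid))
    if (nrow(g) == 0L) return(lab)
    if (any(g$stop > grid@genomeLength))
        stop("annotation coordinates exceed genome length")
    ov <- findOverlaps(windowRanges(grid), IRanges(g$start, g$stop))
    if (length(ov)) {
        byWin <- split(g$name[subjectHits(ov)], queryHits(ov))
        idx <- as.integer(names(byWin))
        lab[idx] <- vapply(byWin, paste, "", collapse = "/")
    }
    lab
}

#' Derive a gene-interval annotation from per-window labels
#'
#' Inverse of \code{\link{annotateWindows}} at window resolution: given the
#' ordered "/"-joined gene labels of a window grid, construct gene intervals
#' that reproduce those labels exactly.  Within a window carrying k gene
#' names, breakpoints are placed at equal spacing; a gene spanning several
#' windows is opened in the first window listing it and closed in the last.
#' Used to package a synthetic annotation consistent with a printed
#' per-window gene column when the underlying gene model is not available.
#'
#' @param grid A \code{WindowGrid}.
#' @param labels Character vector of per-window labels, "/"-joined.
#' @param controlRegion Label denoting "no gene here".
#' @return A \linkS4class{MitoAnnotation}.
#' @export
annotationFromWindowLabels <- function(grid, labels,
                                       controlRegion = "D-Loop") {
    stopifnot(length(labels) == nWindows(grid))
    s <- IRanges::start(windowRanges(grid))
    e <- IRanges::end(windowRanges(grid))
    open <- character(0)   # currently open gene
    openStart <- integer(0)
    out <- list()
    closeGene <- function(name, from, to)
        out[[length(out) + 1L]] <<- data.frame(name = name, start = from,
                                               stop = to, strand = "+",
                                               stringsAsFactors = FALSE)
    for (w in seq_along(labels)) {
        gs <- if (labels[w] == controlRegion) character(0)
              else strsplit(labels[w], "/", fixed = TRUE)[[1]]
        k <- length(gs)
        # breakpoints partition the window into k segments
        bp <- if (k) floor(s[w] + (seq_len(k) - 1) * (e[w] - s[w] + 1) / k)
              else integer(0)
        nxt <- if (w < length(labels) && labels[w + 1L] != controlRegion)
                   strsplit(labels[w + 1L], "/", fixed = TRUE)[[1]]
               else character(0)
        for (i in seq_len(k)) {
            gname <- gs[i]
            if (!length(open) || open != gname) {
                # open a new gene at its segment start
                if (length(open)) {
                    closeGene(open, openStart, bp[i] - 1L)
                    open <- character(0)
                }
                open <- gname
                openStart <- if (i == 1L) s[w] else bp[i]
            }
            if (!(gname %in% nxt) && i < k) {
                closeGene(open, openStart, bp[i + 1L] - 1L)
                open <- character(0)
            } else if (!(gname %in% nxt) && i == k) {
                closeGene(open, openStart, e[w])
                open <- character(0)
            }
        }
        if (k == 0L && length(open)) {
            closeGene(open, openStart, s[w] - 1L)
            open <- character(0)
        }
    }
    if (length(open))
        closeGene(open, openStart, e[length(e)])
    genes <- do.call(rbind, out)
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    new("MitoAnnotation", genes = genes, controlRegion = controlRegion)
}
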