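#' ReferenceGenome: named nucleotide records with a designated mitochondrial
#' sequence
#'
#' Thin wrapper around a \link[Biostrings]{DNAStringSet} that records which
#' sequence is the mitochondrial genome and whether that record is circular.
#' Coordinates throughout the package are 1-based inclusive; by default the
#' mitochondrial record is treated as linear for alignment and windowing even
#' when \code{circular} is \code{TRUE} (the flag is carried so a rotated
#' duplicate reference can be built for circular-aware alignment).
#'
#' @slot sequences A \code{DNAStringSet} of uniquely named records (A/C/G/T/N).
#' @slot mitoName Name of the mitochondrial record, or \code{NA_character_}
#'   when no record is designated (e.g. a nuclear-only reference).
#' @slot circular Circularity flag for the mitochondrial record.
#'
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
    representation(sequences = "DNAStringSet", mitoName = "character",
                   circular = "logical"),
    prototype(mitoName = NA_character_, circular = TRUE))

setValidity("ReferenceGenome", function(object) {
    nm <- names(object@sequences)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        return("all records must be named")
    if (anyDuplicated(nm))
        return("record names must be unique")
    if (length(object@sequences)) {
        ok <- Biostrings::letterFrequency(object@sequences, "ACGTN",
                                          as.prob = FALSE)
        if (any(rowSums(ok) != Biostrings::width(object@sequences)))
            return("sequences must contain only A/C/G/T/N")
    }
    if (length(object@mitoName) != 1L)
        return("mitoName must be a single string (possibly NA)")
    if (!is.na(object@mitoName) && !(object@mitoName %in% nm))
        return("mitoName must name an existing record")
    TRUE
})

#' WindowGrid: non-overlapping tiling of a genome
#'
#' An ordered, contiguous partition of \code{[1, genomeLength]} into windows
#' of \code{windowSize} bases (the last window may be shorter).  Window
#' labels use nominal bounds; see \code{\link{tileWindows}}.
#'
#' @slot ranges An \code{IRanges} of 1-based inclusive windows.
#' @slot windowSize Nominal window width in bases.
#' @slot genomeLength Length of the tiled sequence.
#'
#' @exportClass WindowGrid
setClass("WindowGrid",
    representation(ranges = "IRanges", windowSize = "integer",
                   genomeLength = "integer"))

setValidity("WindowGrid", function(object) {
    r <- object@ranges
    n <- length(r)
    if (n == 0L) return("grid must contain at least one window")
    s <- IRanges::start(r); e <- IRanges::end(r)
    if (s[1] != 1L || e[n] != object@genomeLength)
        return("windows must cover [1, genomeLength]")
    if (n > 1L && any(s[-1] != e[-n] + 1L))
        return("windows must be contiguous and non-overlapping")
    if (any(diff(s) <= 0L)) return("window starts must be strictly increasing")
    w <- e - s + 1L
    if (n > 1L && any(w[-n] != object@windowSize))
        return("all windows except possibly the last must have windowSize bases")
    if (w[n] > object@windowSize)
        return("last window longer than windowSize")
    TRUE
})

#' MitoAnnotation: gene intervals on the mitochondrial genome
#'
#' @slot genes \code{data.frame} with columns \code{name}, \code{start},
#'   \code{stop} (1-based inclusive) and \code{strand}.
#' @slot controlRegion Label applied by \code{\link{annotateWindows}} to
#'   windows overlapping no gene (the mitochondrial control region).
#'
#' @exportClass MitoAnnotation
setClass("MitoAnnotation",
    representation(genes = "data.frame", controlRegion = "character"),
    prototype(controlRegion = "D-Loop"))

setValidity("MitoAnnotation", function(object) {
    g <- object@genes
    need <- c("name", "start", "stop", "strand")
    if (!all(need %in% names(g)))
        return("genes must have columns name, start, stop, strand")
    if (nrow(g)) {
        if (any(g$start < 1L) || any(g$start > g$stop))
            return("gene coordinates must satisfy 1 <= start <= stop")
        if (anyDuplicated(g$name)) return("gene names must be unique")
    }
    TRUE
})

#' TriageReport: per-pass accounting of the NUMT-exclusion triage
#'
#' Fragment counts entering and surviving each of the three passes, plus
#' per-pass discard reasons.  Counts are monotone non-increasing.
#'
#' @slot nInput Fragments entering the triage.
#' @slot nPass1 Fragments uniquely mapped to the mitochondrial record on the
#'   full reference.
#' @slot nPass2 Of those, fragments unmapped on the nuclear-only reference.
#' @slot nPass3 Fragments confirmed mitochondrial-unique on realignment.
#' @slot discards Named list of per-pass discard-reason tables.
#'
#' @exportClass TriageReport
setClass("TriageReport",
    representation(nInput = "integer", nPass1 = "integer", nPass2 = "integer",
                   nPass3 = "integer", discards = "list"))

setValidity("TriageReport", function(object) {
    v <- c(object@nInput, object@nPass1, object@nPass2, object@nPass3)
    if (any(v < 0L)) return("counts must be non-negative")
    if (any(diff(v) > 0L))
        return("pass counts must be monotone non-increasing")
    TRUE
})

#' RetainedReadSet: fragments surviving the triage, with final mitochondrial
#' placements
#'
#' @slot fragments \code{data.frame} with columns \code{read_id}, \code{pos}
#'   (leftmost aligned base of the leftmost mate, 1-based) and \code{span}
#'   (outer fragment span in bases).
#' @slot mitoName Record the placements refer to.
#'
#' @exportClass RetainedReadSet
setClass("RetainedReadSet",
    representation(fragments = "data.frame", mitoName = "character"))

setValidity("RetainedReadSet", function(object) {
    f <- object@fragments
    if (!all(c("read_id", "pos", "span") %in% names(f)))
        return("fragments must have columns read_id, pos, span")
    if (nrow(f) && anyDuplicated(f$read_id))
        return("every retained read has exactly one final alignment")
    if (nrow(f) && any(f$pos < 1L)) return("positions must be >= 1")
    TRUE
})

#' WindowExperiment: samples-by-windows quantification container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with windows as rows
#' and samples as columns.  Assays: \code{counts} (integer fragment counts),
#' \code{rpkm} and, after \code{\link{log2Transform}}, \code{log2rpkm}.
#' \code{rowData} carries the window bounds, gene label and the
#' \code{analyzed} mask (windows failing the coverage filter are ND and are
#' excluded from all statistics).
#'
#' @exportClass WindowExperiment
setClass("WindowExperiment", contains = "SummarizedExperiment")

setValidity("WindowExperiment", function(object) {
    rd <- rowData(object)
    if (!all(c("start", "stop", "analyzed") %in% names(rd)))
        return("rowData must carry start, stop and analyzed")
    if (!"counts" %in% names(assays(object)))
        return("a 'counts' assay is required")
    if (any(assay(object, "counts") < 0)) return("counts must be >= 0")
    TRUE
})
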