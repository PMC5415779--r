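## Toy seed-and-extend aligner (Rcpp back end) and SAM/BAM ingestion.
## Both backends emit the same alignment table; the triage pass logic
## consumes only (read_id, mate, target, pos, mapped, unique, mapq, span).

#' Align reads with the built-in toy aligner
#'
#' Deterministic seed-and-extend alignment: exact k-mer seeds (both
#' strands), ungapped extension scoring mismatches, best placement reported
#' with \code{unique = FALSE} when two or more co-optimal placements exist.
#' Equal-score ties resolve to the leftmost placement (record order, then
#' coordinate), but such reads are non-unique regardless.  Intended for
#' synthetic desk-scale genomes; use an external aligner plus
#' \code{\link{readAlignmentsSam}} for real data.
#'
#' @param reads Named \code{DNAStringSet} (or character vector) of reads.
#' @param ref A \linkS4class{ReferenceGenome}.
#' @param mate Mate index recorded in the output (default 1).
#' @param k Seed length (default 15; must not exceed the read length).
#' @param maxMismatch Maximum mismatches for a reportable placement
#'   (default 5, calibrated to 50 bp reads).
#' @return \code{data.frame} with columns \code{read_id}, \code{mate},
#'   \code{target}, \code{pos}, \code{strand}, \code{mapq}, \code{mapped},
#'   \code{unique}, \code{span}.  Unmapped reads have \code{NA} target/pos.
#' @export
toyAlign <- function(reads, ref, mate = 1L, k = 15L, maxMismatch = 5L) {
    if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
    if (length(reads) && min(width(reads)) < k)
        stop("seed length k exceeds the shortest read")
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    if (length(reads) == 0L)
        return(data.frame(read_id = character(0), mate = integer(0),
                          target = character(0), pos = integer(0),
                          strand = character(0), mapq = integer(0),
                          mapped = logical(0), unique = logical(0),
                          span = integer(0), stringsAsFactors = FALSE))
    res <- .cppAlign(as.character(reads), as.character(refSequences(ref)),
                     as.integer(k), as.integer(maxMismatch))
    uniq <- res$mapped & res$nBest == 1L
    data.frame(read_id = ids, mate = as.integer(mate),
               target = names(refSequences(ref))[res$refIndex],
               pos = res$pos,
               strand = ifelse(res$mapped, ifelse(res$forward, "+", "-"),
                               NA_character_),
               mapq = ifelse(uniq, 37L, 0L),
               mapped = res$mapped, unique = uniq,
               span = ifelse(res$mapped, width(reads), NA_integer_),
               stringsAsFactors = FALSE)
}

#' Import alignments from SAM/BAM
#'
#' Converts any aligner's output into the triage alignment table.  A mate is
#' "unique" when its primary alignment is mapped, has MAPQ > 0 and no
#' secondary records exist for it.
#'
#' @param path SAM (converted via \code{Rsamtools::asBam}) or BAM file.
#' @return Alignment \code{data.frame} as in \code{\link{toyAlign}}.
#' @export
readAlignmentsSam <- function(path) {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE))
        bam <- asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
    p <- ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq",
                               "qwidth"))
    x <- scanBam(bam, param = p)[[1]]
    flag <- x$flag
    isMate2 <- bitwAnd(flag, 128L) > 0L
    isSecondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
    isUnmapped <- bitwAnd(flag, 4L) > 0L
    mate <- ifelse(isMate2, 2L, 1L)
    key <- paste(x$qname, mate)
    nsec <- tapply(isSecondary, key, sum)
    prim <- !isSecondary
    df <- data.frame(read_id = x$qname[prim], mate = mate[prim],
                     target = as.character(x$rname)[prim],
                     pos = x$pos[prim], strand = NA_character_,
                     mapq = x$mapq[prim], mapped = !isUnmapped[prim],
                     span = x$qwidth[prim], stringsAsFactors = FALSE)
    df$target[!df$mapped] <- NA_character_
    df$pos[!df$mapped] <- NA_integer_
    df$unique <- df$mapped & df$mapq > 0L &
        nsec[paste(df$read_id, df$mate)] == 0L
    df[c("read_id", "mate", "target", "pos", "strand", "mapq", "mapped",
         "unique", "span")]
}
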