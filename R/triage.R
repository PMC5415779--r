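## Three-pass NUMT-exclusion triage.
##
## Pass 1: on the full reference, keep fragments uniquely mapped to the
##         mitochondrial record (both mates, in the default pair mode).
## Pass 2: realign the survivors to a nuclear-only reference; keep fragments
##         whose mates are all unmapped there (anything that still maps has
##         a nuclear paralogue and is discarded).
## Pass 3: realign to the full reference and confirm mitochondrial
##         uniqueness; final placements come from this pass.

.pairCollapse <- function(aln, keepMate, pairMode) {
    ok <- tapply(keepMate, aln$read_id,
                 if (pairMode == "both") all else any)
    names(ok)[which(ok)]
}

#' Triage pass 1: unique mitochondrial mapping on the full reference
#'
#' @param alignments Alignment table (from \code{\link{toyAlign}} or
#'   \code{\link{readAlignmentsSam}}) against the \emph{full} reference.
#' @param mitoName Mitochondrial record name.
#' @param minMapq Minimum mapping quality (default 1).
#' @param pairMode "both" (default; every mate must qualify) or "any".
#' @return Character vector of surviving fragment ids.
#' @export
pass1Select <- function(alignments, mitoName, minMapq = 1L,
                        pairMode = c("both", "any")) {
    pairMode <- match.arg(pairMode)
    keep <- alignments$mapped & alignments$unique &
        !is.na(alignments$target) & alignments$target == mitoName &
        alignments$mapq >= minMapq
    sort(.pairCollapse(alignments, keep, pairMode))
}

#' Triage pass 2: exclusion of reads mapping to the nuclear-only reference
#'
#' @param ids Fragment ids surviving pass 1.
#' @param alignmentsNuclear Alignment table against the nuclear-only
#'   reference, covering exactly (at least) those ids.
#' @return Ids whose mates are all unmapped on the nuclear-only reference.
#' @export
pass2Filter <- function(ids, alignmentsNuclear) {
    if (length(ids) == 0L) return(character(0))
    missing <- setdiff(ids, alignmentsNuclear$read_id)
    if (length(missing))
        stop("ids missing from the nuclear alignment set: ",
             paste(head(missing, 3), collapse = ", "))
    a <- alignmentsNuclear[alignmentsNuclear$read_id %in% ids, , drop = FALSE]
    ok <- tapply(!a$mapped, a$read_id, all)
    sort(names(ok)[which(ok)])
}

#' Triage pass 3: confirmation on the full reference
#'
#' Retains fragments again uniquely mapped to the mitochondrial record;
#' final positions are recorded from this pass (leftmost aligned base of the
#' leftmost mate; span = outer mate span).
#'
#' @param ids Fragment ids surviving pass 2.
#' @param alignmentsFull Alignment table against the full reference covering
#'   those ids.
#' @inheritParams pass1Select
#' @return A \linkS4class{RetainedReadSet}.
#' @export
pass3Confirm <- function(ids, alignmentsFull, mitoName, minMapq = 1L,
                         pairMode = c("both", "any")) {
    pairMode <- match.arg(pairMode)
    if (length(ids)) {
        missing <- setdiff(ids, alignmentsFull$read_id)
        if (length(missing))
            stop("ids missing from the confirmation alignment set: ",
                 paste(head(missing, 3), collapse = ", "))
    }
    a <- alignmentsFull[alignmentsFull$read_id %in% ids, , drop = FALSE]
    keepIds <- pass1Select(a, mitoName, minMapq, pairMode)
    a <- a[a$read_id %in% keepIds & a$mapped & a$target == mitoName, ,
           drop = FALSE]
    if (nrow(a)) {
        left <- tapply(a$pos, a$read_id, min)
        right <- tapply(a$pos + a$span - 1L, a$read_id, max)
        frg <- data.frame(read_id = names(left),
                          pos = as.integer(left),
                          span = as.integer(right - left + 1L),
                          stringsAsFactors = FALSE)
        frg <- frg[order(frg$read_id), , drop = FALSE]
        rownames(frg) <- NULL
    } else {
        frg <- data.frame(read_id = character(0), pos = integer(0),
                          span = integer(0), stringsAsFactors = FALSE)
    }
    new("RetainedReadSet", fragments = frg, mitoName = mitoName)
}

#' Accessors for RetainedReadSet and TriageReport
#' @param x Object.
#' @export
retainedFragments <- function(x) x@fragments

#' @rdname retainedFragments
#' @export
triageCounts <- function(x)
    c(input = x@nInput, pass1_mito_unique = x@nPass1,
      pass2_nuclear_unmapped = x@nPass2, pass3_confirmed = x@nPass3)

setMethod("show", "TriageReport", function(object) {
    cat("TriageReport\n")
    v <- triageCounts(object)
    for (i in seq_along(v)) cat(sprintf("  %-24s %d\n", names(v)[i], v[i]))
})

setMethod("show", "RetainedReadSet", function(object) {
    cat(sprintf("RetainedReadSet: %d fragments on %s\n",
                nrow(object@fragments), object@mitoName))
})

#' Run the full three-pass triage
#'
#' @param mate1,mate2 Named \code{DNAStringSet}s of trimmed mates (equal
#'   names define fragments).  \code{mate2} may be \code{NULL} for
#'   single-end input.
#' @param fullRef Full \code{ReferenceGenome} (mitochondrial record set).
#' @param nuclearRef Nuclear-only reference, typically
#'   \code{buildNuclearOnly(fullRef)}.  Must not contain the mitochondrial
#'   record.
#' @param minMapq,pairMode Passed to the pass functions.
#' @param k,maxMismatch Toy-aligner parameters.
#' @return List with \code{retained} (a \linkS4class{RetainedReadSet}) and
#'   \code{report} (a \linkS4class{TriageReport}).
#' @export
runTriage <- function(mate1, mate2 = NULL, fullRef, nuclearRef,
                      minMapq = 1L, pairMode = c("both", "any"),
                      k = 15L, maxMismatch = 5L) {
    pairMode <- match.arg(pairMode)
    if (is.na(mitoName(fullRef)))
        stop("full reference must designate a mitochondrial record")
    if (mitoName(fullRef) %in% names(refSequences(nuclearRef)))
        stop("nuclear-only reference still contains the mitochondrial record")
    mito <- mitoName(fullRef)

    alignBoth <- function(ref, ids = NULL) {
        m1 <- mate1; m2 <- mate2
        if (!is.null(ids)) {
            m1 <- m1[names(m1) %in% ids]
            if (!is.null(m2)) m2 <- m2[names(m2) %in% ids]
        }
        a <- toyAlign(m1, ref, mate = 1L, k = k, maxMismatch = maxMismatch)
        if (!is.null(m2))
            a <- rbind(a, toyAlign(m2, ref, mate = 2L, k = k,
                                   maxMismatch = maxMismatch))
        a
    }

    nIn <- length(mate1)
    aFull <- alignBoth(fullRef)
    p1 <- pass1Select(aFull, mito, minMapq, pairMode)
    aNuc <- alignBoth(nuclearRef, ids = p1)
    p2 <- if (length(p1)) pass2Filter(p1, aNuc) else character(0)
    aConf <- alignBoth(fullRef, ids = p2)
    retained <- pass3Confirm(p2, aConf, mito, minMapq, pairMode)

    disc <- list(
        pass1 = c(not_mito_unique = nIn - length(p1)),
        pass2 = c(mapped_nuclear = length(p1) - length(p2)),
        pass3 = c(not_confirmed = length(p2) -
                      nrow(retainedFragments(retained))))
    report <- new("TriageReport", nInput = as.integer(nIn),
                  nPass1 = length(p1), nPass2 = length(p2),
                  nPass3 = nrow(retainedFragments(retained)),
                  discards = disc)
    list(retained = retained, report = report)
}

#' Export triage outputs as TSV
#' @param x A \code{RetainedReadSet} or \code{TriageReport}.
#' @param path Output file.
#' @export
writeTriageTsv <- function(x, path) {
    if (is(x, "RetainedReadSet")) {
        write.table(retainedFragments(x), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else {
        v <- triageCounts(x)
        write.table(data.frame(pass = names(v), fragments = as.integer(v)),
                    path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
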