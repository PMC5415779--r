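## Adapter and quality trimming of paired-end reads before alignment.

#' Trim one read: 3' adapter removal then 3' quality trimming
#'
#' Adapter trimming removes the read suffix from the leftmost position at
#' which the remaining suffix exactly matches a prefix of the adapter of at
#' least \code{minOverlap} bases.  Quality trimming then removes the 3'
#' suffix chosen by the maximal-partial-sum rule over
#' \code{(qThreshold - q_i)}: among all suffixes, the one with the largest
#' positive sum of \code{qThreshold - q_i} is removed (ties broken towards
#' trimming more).  A hard-clip mode that cuts at the first base with
#' quality below the threshold is available instead.
#'
#' @param seq Read sequence (single character string).
#' @param quals Integer vector of per-base Phred qualities.
#' @param adapter Adapter sequence, or \code{NULL} to skip adapter trimming.
#' @param qThreshold Phred quality threshold (default 20).
#' @param minOverlap Minimum adapter overlap at the 3' end (default 5).
#' @param minLength Reads trimmed below this length are flagged discarded
#'   (default 30).
#' @param mode "maxsum" (default) or "hardclip".
#' @return List with \code{seq}, \code{quals}, \code{discarded} and
#'   \code{basesTrimmed}.
#' @export
trimRead <- function(seq, quals, adapter = NULL, qThreshold = 20L,
                     minOverlap = 5L, minLength = 30L,
                     mode = c("maxsum", "hardclip")) {
    mode <- match.arg(mode)
    stopifnot(nchar(seq) == length(quals))
    if (!is.null(adapter) && nchar(adapter) == 0L)
        stop("adapter must be non-empty when adapter trimming is enabled")
    n0 <- nchar(seq)

    if (!is.null(adapter) && n0 >= minOverlap) {
        ad <- toupper(adapter)
        for (p in seq_len(n0 - minOverlap + 1L)) {
            ov <- min(n0 - p + 1L, nchar(ad))
            if (substr(seq, p, p + ov - 1L) == substr(ad, 1L, ov)) {
                seq <- substr(seq, 1L, p - 1L)
                quals <- quals[seq_len(p - 1L)]
                break
            }
        }
    }

    n <- nchar(seq)
    if (n > 0L) {
        if (mode == "maxsum") {
            sfx <- rev(cumsum(rev(qThreshold - quals)))  # sum over suffix i..n
            if (any(sfx > 0)) {
                cut <- which.max(sfx)   # earliest maximal sum: trims most
                seq <- substr(seq, 1L, cut - 1L)
                quals <- quals[seq_len(cut - 1L)]
            }
        } else {
            low <- which(quals < qThreshold)
            if (length(low)) {
                seq <- substr(seq, 1L, low[1] - 1L)
                quals <- quals[seq_len(low[1] - 1L)]
            }
        }
    }
    list(seq = seq, quals = quals, discarded = nchar(seq) < minLength,
         basesTrimmed = n0 - nchar(seq))
}

.phredToInt <- function(q, offset = 33L) utf8ToInt(q) - offset
.intToPhred <- function(q, offset = 33L) intToUtf8(q + offset)

#' Trim a pair of FASTQ files
#'
#' Reads two synchronized FASTQ files (gzip-aware), trims every mate with
#' \code{\link{trimRead}} and returns the surviving pairs plus a QC report.
#' A pair is discarded when either trimmed mate falls below the minimum
#' length.
#'
#' @param fastq1,fastq2 Paths to mate-1 and mate-2 FASTQ files.
#' @param adapter Adapter sequence or \code{NULL}.
#' @param qThreshold,minOverlap,minLength,mode Passed to
#'   \code{\link{trimRead}}.
#' @param phredOffset FASTQ quality encoding offset (default 33).
#' @return List with \code{mate1}, \code{mate2}
#'   (\code{QualityScaledDNAStringSet}s of kept pairs) and \code{report}
#'   (reads in, pairs kept/discarded, bases trimmed).
#' @export
qcReadPairs <- function(fastq1, fastq2, adapter = NULL, qThreshold = 20L,
                        minOverlap = 5L, minLength = 30L,
                        mode = c("maxsum", "hardclip"), phredOffset = 33L) {
    mode <- match.arg(mode)
    readFq <- function(p) {
        if (length(readLines(p, n = 1L)) == 0L)
            return(QualityScaledDNAStringSet(DNAStringSet(),
                                             PhredQuality(character(0))))
        # the reader notes dropped (empty) FASTQ metadata columns; benign
        suppressWarnings(readQualityScaledDNAStringSet(p))
    }
    r1 <- readFq(fastq1)
    r2 <- readFq(fastq2)
    if (length(r1) != length(r2))
        stop("desynchronized mate files: ", length(r1), " vs ", length(r2),
             " reads")
    id1 <- sub("\\s.*$", "", names(r1))
    id2 <- sub("\\s.*$", "", names(r2))
    if (!identical(id1, id2))
        stop("desynchronized mate files: read ids differ")
    n <- length(r1)
    if (n == 0L)
        return(list(mate1 = r1, mate2 = r2,
                    report = data.frame(readsIn = 0L, pairsKept = 0L,
                                        pairsDiscarded = 0L,
                                        basesTrimmed = 0L)))
    trimSet <- function(rs) {
        seqs <- as.character(rs)
        qs <- as.character(quality(rs))
        out <- vector("list", length(seqs))
        for (i in seq_along(seqs))
            out[[i]] <- trimRead(seqs[i], .phredToInt(qs[i], phredOffset),
                                 adapter = adapter, qThreshold = qThreshold,
                                 minOverlap = minOverlap,
                                 minLength = minLength, mode = mode)
        out
    }
    t1 <- trimSet(r1)
    t2 <- trimSet(r2)
    disc <- vapply(t1, `[[`, TRUE, "discarded") |
            vapply(t2, `[[`, TRUE, "discarded")
    trimmed <- sum(vapply(t1, `[[`, 0L, "basesTrimmed")) +
               sum(vapply(t2, `[[`, 0L, "basesTrimmed"))
    keep <- which(!disc)
    mk <- function(tt, ids) {
        s <- DNAStringSet(vapply(tt, `[[`, "", "seq")[keep])
        q <- PhredQuality(vapply(tt, function(x) .intToPhred(x$quals), "")[keep])
        names(s) <- ids[keep]
        # benign note about dropped (empty) metadata columns
        suppressWarnings(QualityScaledDNAStringSet(s, q))
    }
    list(mate1 = mk(t1, id1), mate2 = mk(t2, id2),
         report = data.frame(readsIn = n, pairsKept = length(keep),
                             pairsDiscarded = sum(disc),
                             basesTrimmed = trimmed))
}

#' Write a pair of FASTQ files
#'
#' @param mate1,mate2 \code{QualityScaledDNAStringSet}s (or
#'   \code{DNAStringSet}s, in which case a constant quality is written).
#' @param path1,path2 Output paths; a ".gz" suffix compresses.
#' @param constantQ Quality used when inputs carry none (default 30).
#' @export
writeFastqPair <- function(mate1, mate2, path1, path2, constantQ = 30L) {
    wr <- function(x, p) {
        if (is(x, "QualityScaledDNAStringSet")) {
            Biostrings::writeQualityScaledXStringSet(
                x, p, compress = grepl("\\.gz$", p))
        } else {
            q <- PhredQuality(vapply(width(x), function(w)
                .intToPhred(rep(constantQ, w)), ""))
            writeXStringSet(x, p, format = "fastq", qualities = q,
                            compress = grepl("\\.gz$", p))
        }
    }
    wr(mate1, path1); wr(mate2, path2)
    invisible(c(path1, path2))
}
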