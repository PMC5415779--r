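# Shared helpers: tiny deterministic references, reads and containers built
# in code at test time.

randomDna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small full/nuclear reference pair with no homology between records
tinyRefPair <- function(mitoLen = 2000, nucLen = 3000, seed = 42) {
    set.seed(seed)
    full <- referenceGenome(c(chr1 = randomDna(nucLen),
                              chrM = randomDna(mitoLen)))
    list(full = full, nuclear = buildNuclearOnly(full))
}

# extract reads (verbatim substrings) from a reference record
readsFrom <- function(ref, record, starts, len = 50, prefix = "r") {
    seqs <- vapply(starts, function(s)
        substr(as.character(refSequences(ref)[[record]]), s, s + len - 1), "")
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0(prefix, seq_along(starts))
    out
}

# WindowExperiment from a counts matrix with a paired tissue design
makeTinyWE <- function(counts, tissues, individuals, windowSize = 100) {
    grid <- tileWindows(nrow(counts) * windowSize, windowSize)
    buildWindowExperiment(counts, grid,
                          data.frame(individual = individuals,
                                     tissue = tissues),
                          minCount = 10L)
}

# independent textbook paired-t oracle (closed form, no t.test)
oraclePairedT <- function(x, y) {
    d <- x - y
    n <- length(d)
    tstat <- mean(d) / (sd(d) / sqrt(n))
    list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1), delta = mean(d))
}

# independent maximal-partial-sum trimming oracle: enumerate all suffixes
oracleQualTrim <- function(quals, thr) {
    n <- length(quals)
    if (n == 0) return(0L)
    sums <- vapply(seq_len(n), function(k) sum(thr - quals[k:n]), 0)
    if (all(sums <= 0)) return(0L)            # nothing trimmed
    n - min(which(sums == max(sums))) + 1L    # bases removed
}

writeTestFastq <- function(seqs, quals, path) {
    stopifnot(length(seqs) == length(quals))
    con <- file(path, "w")
    for (i in seq_along(seqs))
        writeLines(c(paste0("@", names(seqs)[i]), seqs[i], "+",
                     intToUtf8(quals[[i]] + 33L)), con)
    close(con)
    path
}
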