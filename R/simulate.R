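## Synthetic-data generator: reference genomes with planted NUMTs,
## per-tissue methylomes with planted DMRs, and MeDIP-seq-like paired-end
## reads with per-read truth labels.  Everything is seeded and byte-
## reproducible; the generator's defaults are the package's reference study
## conditions (see the methods vignette).

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a 16,569 bp
#' circular mitochondrial genome, a nuclear decoy with one identical and one
#' 10 percent-diverged NUMT, seven tissues (five cortical regions,
#' cerebellum, blood) across three individuals with blood missing for
#' individual 2, MeDIP fragments of 220-320 bp sequenced as 50 bp
#' paired-end reads, and fragment enrichment proportional to the
#' methylation of the window containing the fragment midpoint
#' (weight = baseWeight + slope x methylation).
#'
#' @param mitoLength Mitochondrial genome length (default 16569).
#' @param nuclearLengths Named lengths of nuclear decoy records.
#' @param numts \code{data.frame} with columns \code{src_start},
#'   \code{src_end} (mitochondrial source interval), \code{chrom},
#'   \code{insert_pos} (insertion locus on the pre-insertion nuclear
#'   sequence), \code{divergence} (per-base substitution probability).
#' @param tissues Tissue labels; \code{cortexTissues} marks which are
#'   cortical.
#' @param individuals Number of individuals.
#' @param missing \code{data.frame(individual, tissue)} of absent samples.
#' @param baselineMeth Baseline per-window methylation in [0, 1].
#' @param noiseSd Individual-level Gaussian noise sd on methylation.
#' @param dmrs Planted effects: \code{data.frame(start, end, tissue,
#'   effect)}; \code{tissue = "cortex"} expands to all cortical tissues.
#' @param baseWeight,enrichSlope Fragment sampling weight parameters.
#' @param fragmentRange Fragment length range in bp (default 220-320).
#' @param readLength Read length (default 50).
#' @param errorRate Per-base sequencing substitution rate.
#' @param numtFraction Fraction of fragments drawn from NUMT loci
#'   (contamination; default 0.2).
#' @param windowSize Analysis window size (default 100).
#' @return A validated configuration list (class "SimulationConfig").
#' @export
simulationConfig <- function(mitoLength = 16569L,
                             nuclearLengths = c(chr1 = 60000L),
                             numts = data.frame(
                                 src_start = c(5001L, 12001L),
                                 src_end = c(7000L, 13000L),
                                 chrom = "chr1",
                                 insert_pos = c(15000L, 40000L),
                                 divergence = c(0, 0.10)),
                             tissues = c("BA8", "BA9", "BA10", "ECX", "STG",
                                         "CER", "BLD"),
                             cortexTissues = c("BA8", "BA9", "BA10", "ECX",
                                               "STG"),
                             individuals = 3L,
                             missing = data.frame(individual = 2L,
                                                  tissue = "BLD"),
                             baselineMeth = 0.2, noiseSd = 0.05,
                             dmrs = data.frame(
                                 start = c(16201L, 2201L),
                                 end = c(16600L, 2600L),
                                 tissue = c("cortex", "CER"),
                                 effect = c(0.3, 0.3)),
                             baseWeight = 0.1, enrichSlope = 1.0,
                             fragmentRange = c(220L, 320L),
                             readLength = 50L, errorRate = 0.001,
                             numtFraction = 0.2, windowSize = 100L) {
    cfg <- list(mitoLength = as.integer(mitoLength),
                nuclearLengths = nuclearLengths, numts = numts,
                tissues = tissues, cortexTissues = cortexTissues,
                individuals = as.integer(individuals), missing = missing,
                baselineMeth = baselineMeth, noiseSd = noiseSd, dmrs = dmrs,
                baseWeight = baseWeight, enrichSlope = enrichSlope,
                fragmentRange = as.integer(fragmentRange),
                readLength = as.integer(readLength), errorRate = errorRate,
                numtFraction = numtFraction,
                windowSize = as.integer(windowSize))
    stopifnot(cfg$baselineMeth >= 0, cfg$baselineMeth <= 1,
              cfg$noiseSd >= 0, cfg$errorRate >= 0, cfg$errorRate < 1,
              cfg$numtFraction >= 0, cfg$numtFraction <= 1,
              cfg$baseWeight >= 0, length(cfg$fragmentRange) == 2L,
              cfg$fragmentRange[1] <= cfg$fragmentRange[2],
              cfg$fragmentRange[2] <= cfg$mitoLength,
              cfg$readLength <= cfg$fragmentRange[1])
    if (nrow(cfg$numts)) {
        stopifnot(all(cfg$numts$src_start >= 1),
                  all(cfg$numts$src_end <= cfg$mitoLength),
                  all(cfg$numts$divergence >= 0),
                  all(cfg$numts$divergence <= 1),
                  all(cfg$numts$chrom %in% names(cfg$nuclearLengths)))
    }
    structure(cfg, class = "SimulationConfig")
}

.randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

.mutateSeq <- function(seq, rate) {
    if (rate == 0) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
}

#' Simulate the reference genomes
#'
#' Generates a random mitochondrial sequence (or uses one supplied), plants
#' each NUMT by mutating its mitochondrial source interval i.i.d. at the
#' configured divergence and inserting it at its locus, and derives the
#' nuclear-only reference with \code{\link{buildNuclearOnly}}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed (all randomness is drawn after \code{set.seed}).
#' @param mitoSeq Optional mitochondrial sequence (character) to use
#'   instead of a random one.
#' @return List with \code{full} and \code{nuclear}
#'   (\code{ReferenceGenome}s) and \code{truth}: the planted NUMT
#'   coordinates on the final nuclear records.
#' @export
simulateReference <- function(config, seed = 1L, mitoSeq = NULL) {
    set.seed(seed)
    mito <- if (is.null(mitoSeq)) .randomSeq(config$mitoLength)
            else toupper(mitoSeq)
    stopifnot(nchar(mito) == config$mitoLength)
    nuc <- lapply(config$nuclearLengths, .randomSeq)
    numts <- config$numts
    truth <- NULL
    if (nrow(numts)) {
        if (anyDuplicated(numts[c("chrom", "insert_pos")]))
            stop("overlapping NUMT insertion loci")
        rows <- list()
        for (ch in names(nuc)) {
            nn <- numts[numts$chrom == ch, , drop = FALSE]
            if (!nrow(nn)) next
            nn <- nn[order(nn$insert_pos), , drop = FALSE]
            seq <- nuc[[ch]]
            offset <- 0L
            for (i in seq_len(nrow(nn))) {
                frag <- .mutateSeq(substr(mito, nn$src_start[i],
                                          nn$src_end[i]),
                                   nn$divergence[i])
                at <- nn$insert_pos[i] + offset
                seq <- paste0(substr(seq, 1L, at - 1L), frag,
                              substr(seq, at, nchar(seq)))
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = ch, start = at, end = at + nchar(frag) - 1L,
                    src_start = nn$src_start[i], src_end = nn$src_end[i],
                    divergence = nn$divergence[i],
                    stringsAsFactors = FALSE)
                offset <- offset + nchar(frag)
            }
            nuc[[ch]] <- seq
        }
        truth <- do.call(rbind, rows)
    }
    seqs <- DNAStringSet(c(unlist(nuc), chrM = mito))
    full <- referenceGenome(seqs, mitoName = "chrM", circular = TRUE)
    list(full = full, nuclear = buildNuclearOnly(full),
         truth = list(numts = truth))
}

#' Simulate per-tissue, per-individual window methylomes
#'
#' Window methylation = baseline + planted tissue effect + individual-level
#' Gaussian noise, clipped to [0, 1].
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return List with \code{meth} (array windows x tissues x individuals),
#'   \code{grid} and \code{dmrs} (the planted-effect table with expanded
#'   tissue labels).
#' @export
simulateMethylomes <- function(config, seed = 1L) {
    set.seed(seed)
    grid <- tileWindows(config$mitoLength, config$windowSize)
    nw <- nWindows(grid)
    expand <- function(tt) if (tt == "cortex") config$cortexTissues else tt
    effects <- matrix(0, nw, length(config$tissues),
                      dimnames = list(NULL, config$tissues))
    dmrs <- config$dmrs
    if (nrow(dmrs)) {
        for (i in seq_len(nrow(dmrs))) {
            wsel <- windowStarts(grid) >= dmrs$start[i] &
                windowStarts(grid) <= dmrs$end[i]
            for (tt in expand(dmrs$tissue[i]))
                effects[wsel, tt] <- effects[wsel, tt] + dmrs$effect[i]
        }
    }
    meth <- array(NA_real_, c(nw, length(config$tissues),
                              config$individuals),
                  dimnames = list(NULL, config$tissues,
                                  paste0("ind", seq_len(config$individuals))))
    for (ind in seq_len(config$individuals))
        for (ti in seq_along(config$tissues))
            meth[, ti, ind] <- pmin(1, pmax(0,
                config$baselineMeth + effects[, ti] +
                    rnorm(nw, sd = config$noiseSd)))
    list(meth = meth, grid = grid, dmrs = dmrs, effects = effects)
}

## enrichment-weighted fragment start/length sampling (shared by the
## sequence-level and count-level paths); meth is the per-window methylation
## of the sample being sequenced
.sampleFragments <- function(meth, config, n) {
    L <- config$mitoLength
    winW <- config$baseWeight + config$enrichSlope * meth
    if (any(winW <= 0)) stop("enrichment weights must be positive")
    pw <- winW[(seq_len(L) - 1L) %/% config$windowSize + 1L]
    lens <- sample(seq.int(config$fragmentRange[1], config$fragmentRange[2]),
                   n, replace = TRUE)
    starts <- integer(n)
    for (l in unique(lens)) {
        sel <- which(lens == l)
        ns <- L - l + 1L
        w <- pw[seq_len(ns) + l %/% 2L]   # weight of the midpoint's window
        starts[sel] <- sample.int(ns, length(sel), replace = TRUE, prob = w)
    }
    list(start = starts, len = lens)
}

.applyErrors <- function(seqs, rate) {
    if (rate == 0 || length(seqs) == 0L) return(seqs)
    wd <- nchar(seqs)
    stopifnot(length(unique(wd)) == 1L)
    nerr <- stats::rbinom(1L, length(seqs) * wd[1], rate)
    if (nerr == 0L) return(seqs)
    pos <- sample.int(length(seqs) * wd[1], nerr)
    ri <- (pos - 1L) %/% wd[1] + 1L
    pi <- (pos - 1L) %% wd[1] + 1L
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(nerr)) {
        cur <- substr(seqs[ri[j]], pi[j], pi[j])
        substr(seqs[ri[j]], pi[j], pi[j]) <-
            sample(setdiff(bases, cur), 1L)
    }
    seqs
}

#' Simulate MeDIP-seq paired-end reads for one sample
#'
#' Fragments are drawn from the mitochondrial genome (and, at
#' \code{numtFraction}, from planted NUMT loci) with length uniform in the
#' configured range and start weighted by the enrichment weight of the
#' window containing the fragment midpoint.  The two mates are the
#' fragment's first \code{readLength} bases (forward) and the
#' reverse-complement of its last \code{readLength} bases; i.i.d.
#' substitution errors are applied at \code{errorRate} and Phred strings
#' match that rate.
#'
#' @param refs Output of \code{\link{simulateReference}}.
#' @param meth Per-window methylation vector for this sample (e.g. a slice
#'   of \code{\link{simulateMethylomes}}).
#' @param config A \code{\link{simulationConfig}}.
#' @param nFragments Number of fragments.
#' @param seed Integer seed.
#' @param sampleId Prefix for read ids.
#' @return List with \code{mate1}, \code{mate2} (named
#'   \code{DNAStringSet}s), \code{truth} (per-read origin labels and source
#'   coordinates) and \code{quality} (constant Phred value consistent with
#'   the error rate).
#' @export
simulateMedipReads <- function(refs, meth, config, nFragments = 10000L,
                               seed = 1L, sampleId = "s1") {
    set.seed(seed)
    L <- config$mitoLength
    if (config$fragmentRange[2] > L)
        stop("fragment range exceeds mitochondrial length")
    numts <- refs$truth$numts
    nNumt <- if (!is.null(numts) && nrow(numts) && config$numtFraction > 0)
        stats::rbinom(1L, nFragments, config$numtFraction) else 0L
    nMito <- nFragments - nNumt

    fr <- .sampleFragments(meth, config, nMito)
    mitoSeq <- as.character(mitoSequence(refs$full))
    origin <- rep("mito", nMito)
    chrom <- rep("chrM", nMito)
    starts <- fr$start
    lens <- fr$len

    if (nNumt > 0L) {
        lensN <- sample(seq.int(config$fragmentRange[1],
                                config$fragmentRange[2]),
                        nNumt, replace = TRUE)
        row <- sample.int(nrow(numts), nNumt, replace = TRUE,
                          prob = numts$end - numts$start + 1)
        startN <- numts$start[row] +
            floor(runif(nNumt) * (numts$end[row] - numts$start[row] -
                                      lensN + 2))
        origin <- c(origin, rep("numt", nNumt))
        chrom <- c(chrom, numts$chrom[row])
        starts <- c(starts, startN)
        lens <- c(lens, lensN)
    }

    nuclearSeqs <- as.character(refSequences(refs$nuclear))
    getFrag <- function(i) {
        src <- if (origin[i] == "mito") mitoSeq else nuclearSeqs[[chrom[i]]]
        substr(src, starts[i], starts[i] + lens[i] - 1L)
    }
    frags <- vapply(seq_along(starts), getFrag, "")
    rl <- config$readLength
    m1 <- substr(frags, 1L, rl)
    m2 <- as.character(reverseComplement(DNAStringSet(
        substr(frags, lens - rl + 1L, lens))))
    m1 <- .applyErrors(m1, config$errorRate)
    m2 <- .applyErrors(m2, config$errorRate)
    ids <- sprintf("%s_frag%06d", sampleId, seq_along(m1))
    mate1 <- DNAStringSet(m1); names(mate1) <- ids
    mate2 <- DNAStringSet(m2); names(mate2) <- ids
    q <- max(2L, min(40L, as.integer(round(-10 * log10(
        max(config$errorRate, 1e-4))))))
    truth <- data.frame(read_id = ids, origin = origin, chrom = chrom,
                        pos = starts, fragLen = lens,
                        stringsAsFactors = FALSE)
    list(mate1 = mate1, mate2 = mate2, truth = truth, quality = q)
}

#' Simulate window fragment counts directly
#'
#' The count-level marginal of \code{\link{simulateMedipReads}}: fragments
#' are sampled with the same enrichment-weighted start distribution and
#' tabulated by the window of their leftmost base, skipping sequence
#' generation.  Used for power studies where only counts matter.
#'
#' @inheritParams simulateMedipReads
#' @return Integer vector of per-window fragment counts.
#' @export
simulateWindowCounts <- function(meth, config, nFragments = 50000L,
                                 seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    fr <- .sampleFragments(meth, config, nFragments)
    grid <- tileWindows(config$mitoLength, config$windowSize)
    as.integer(tabulate((fr$start - 1L) %/% config$windowSize + 1L,
                        nbins = nWindows(grid)))
}

#' Simulate the full study design at count level
#'
#' One methylome per (tissue, individual) sample minus the configured
#' missing combinations, each sequenced to \code{nFragments} fragments, and
#' assembled into a \code{\link{buildWindowExperiment}} input.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param nFragments Fragments per sample.
#' @param seed Integer seed.
#' @param minCount,scope Coverage-filter settings.
#' @return List with \code{we} (a \code{WindowExperiment}), \code{truth}
#'   (the methylome simulation) and \code{samples}.
#' @export
simulateStudyCounts <- function(config, nFragments = 50000L, seed = 1L,
                                minCount = 10L, scope = "all") {
    sim <- simulateMethylomes(config, seed = seed)
    smp <- expand.grid(individual = seq_len(config$individuals),
                       tissue = config$tissues,
                       stringsAsFactors = FALSE)
    drop <- rep(FALSE, nrow(smp))
    if (nrow(config$missing))
        for (i in seq_len(nrow(config$missing)))
            drop <- drop | (smp$individual == config$missing$individual[i] &
                            smp$tissue == config$missing$tissue[i])
    smp <- smp[!drop, , drop = FALSE]
    rownames(smp) <- NULL
    counts <- matrix(0L, nWindows(sim$grid), nrow(smp))
    colnames(counts) <- paste0(smp$tissue, "_ind", smp$individual)
    for (i in seq_len(nrow(smp)))
        counts[, i] <- simulateWindowCounts(
            sim$meth[, smp$tissue[i], smp$individual[i]], config,
            nFragments = nFragments)
    we <- buildWindowExperiment(counts, sim$grid, smp,
                                minCount = minCount, scope = scope)
    list(we = we, truth = sim, samples = smp)
}

#' Classify grid windows relative to the planted DMR regions
#'
#' Enrichment acts on the window containing the fragment \emph{midpoint}
#' while counting assigns fragments to the window of their leftmost base,
#' so a planted region influences the counts of windows up to half a
#' fragment length upstream.  A window is \code{informative} for the
#' planted effect when every fragment starting in it has its midpoint
#' inside a planted region (and fragment starts are geometrically possible
#' there), \code{affected} when some midpoints fall inside a region, and
#' \code{null} otherwise.  Power is assessed on informative windows and
#' specificity on null windows.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return Character vector over grid windows: "informative", "affected"
#'   or "null".
#' @export
plantedWindowStatus <- function(config) {
    grid <- tileWindows(config$mitoLength, config$windowSize)
    s <- windowStarts(grid)
    e <- pmin(s + config$windowSize - 1L, config$mitoLength)
    loMid <- s + config$fragmentRange[1] %/% 2L
    hiMid <- e + config$fragmentRange[2] %/% 2L
    feasible <- s <= config$mitoLength - config$fragmentRange[1] + 1L
    status <- rep("null", nWindows(grid))
    expand <- function(tt) if (tt == "cortex") config$cortexTissues else tt
    dmrs <- config$dmrs
    for (i in seq_len(nrow(dmrs))) {
        rs <- dmrs$start[i]
        re <- min(dmrs$end[i], config$mitoLength)
        touches <- hiMid >= rs & loMid <= re
        status[touches] <- "affected"
    }
    for (i in seq_len(nrow(dmrs))) {
        rs <- dmrs$start[i]
        re <- min(dmrs$end[i], config$mitoLength)
        inside <- loMid >= rs & hiMid <= re & feasible
        status[inside] <- "informative"
    }
    status[!feasible & status == "null"] <- "affected"  # never receives starts
    status
}

#' Score a triage run against simulation truth
#'
#' @param truth Per-read truth table from \code{\link{simulateMedipReads}}.
#' @param retained A \linkS4class{RetainedReadSet}.
#' @return List with \code{precision} (fraction of retained reads truly
#'   mitochondrial; \code{NA} with a warning when nothing is retained),
#'   \code{recall} (fraction of mitochondrial-origin reads retained) and the
#'   underlying counts.
#' @export
evaluateTriage <- function(truth, retained) {
    ids <- retainedFragments(retained)$read_id
    unknown <- setdiff(ids, truth$read_id)
    if (length(unknown))
        stop("retained read ids missing from truth: ",
             paste(head(unknown, 3), collapse = ", "))
    isMito <- truth$origin == "mito"
    nRet <- length(ids)
    tp <- sum(truth$read_id[isMito] %in% ids)
    precision <- if (nRet == 0L) {
        warning("empty retained set; precision undefined")
        NA_real_
    } else tp / nRet
    recall <- if (sum(isMito) == 0L) NA_real_ else tp / sum(isMito)
    list(precision = precision, recall = recall, nRetained = nRet,
         nMitoTruth = sum(isMito), nTruePositive = tp)
}
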