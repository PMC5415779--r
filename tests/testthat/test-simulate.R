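smallCfg <- function(...) {
    simulationConfig(mitoLength = 4000L,
                     nuclearLengths = c(chr1 = 8000L),
                     numts = data.frame(src_start = 1001L, src_end = 2000L,
                                        chrom = "chr1", insert_pos = 3000L,
                                        divergence = 0),
                     dmrs = data.frame(start = integer(0), end = integer(0),
                                       tissue = character(0),
                                       effect = numeric(0)),
                     ...)
}

test_that("reference simulation plants NUMTs at the stated divergence", {
    cfg <- smallCfg()
    refs <- simulateReference(cfg, seed = 1)
    expect_identical(names(refSequences(refs$full)), c("chr1", "chrM"))
    expect_identical(names(refSequences(refs$nuclear)), "chr1")
    tr <- refs$truth$numts
    expect_equal(tr$end - tr$start + 1, 1000)
    mito <- as.character(mitoSequence(refs$full))
    nucl <- as.character(refSequences(refs$full)[["chr1"]])
    # divergence 0: the planted copy is identical to its source interval
    expect_identical(substr(nucl, tr$start, tr$end),
                     substr(mito, tr$src_start, tr$src_end))
    # insertion grows the nuclear record by the NUMT length
    expect_equal(nchar(nucl), 8000 + 1000)

    # 10% divergence: observed mismatch fraction within 3 binomial sd
    cfgD <- smallCfg()
    cfgD$numts$divergence <- 0.1
    refsD <- simulateReference(cfgD, seed = 1)
    trD <- refsD$truth$numts
    a <- strsplit(substr(as.character(refSequences(refsD$full)[["chr1"]]),
                         trD$start, trD$end), "")[[1]]
    b <- strsplit(substr(as.character(mitoSequence(refsD$full)),
                         trD$src_start, trD$src_end), "")[[1]]
    mm <- mean(a != b)
    # substitution to a different base, so observed rate estimates 0.1
    expect_lt(abs(mm - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))

    # determinism
    refs2 <- simulateReference(cfg, seed = 1)
    expect_identical(as.character(refSequences(refs2$full)),
                     as.character(refSequences(refs$full)))

    cfgBad <- smallCfg()
    cfgBad$numts <- rbind(cfgBad$numts, cfgBad$numts)
    expect_error(simulateReference(cfgBad, seed = 1), "overlap")
})

test_that("methylome simulation plants effects and calibrated noise", {
    cfg <- simulationConfig(noiseSd = 0,
                            dmrs = data.frame(start = integer(0),
                                              end = integer(0),
                                              tissue = character(0),
                                              effect = numeric(0)))
    sim <- simulateMethylomes(cfg, seed = 1)
    # zero noise, no DMRs: every tissue and individual identical
    expect_true(all(sim$meth == cfg$baselineMeth))

    cfg2 <- simulationConfig(noiseSd = 0,
                             dmrs = data.frame(start = 16001L, end = 16600L,
                                               tissue = "cortex",
                                               effect = 0.3))
    sim2 <- simulateMethylomes(cfg2, seed = 1)
    g <- sim2$grid
    planted <- windowStarts(g) >= 16001
    diffs <- sim2$meth[, "BA8", 1] - sim2$meth[, "CER", 1]
    expect_true(all(diffs[planted] == 0.3))
    expect_true(all(diffs[!planted] == 0))
    # cerebellum itself is untouched
    expect_true(all(sim2$meth[, "CER", ] == cfg2$baselineMeth))

    # noise sd recovered within 20% by Monte Carlo
    cfg3 <- simulationConfig(noiseSd = 0.05, individuals = 60L,
                             dmrs = data.frame(start = integer(0),
                                               end = integer(0),
                                               tissue = character(0),
                                               effect = numeric(0)))
    sim3 <- simulateMethylomes(cfg3, seed = 1)
    sds <- apply(sim3$meth[1:50, "BA8", ], 1, sd)
    expect_lt(abs(mean(sds) - 0.05), 0.2 * 0.05)
})

test_that("read simulation follows the enrichment model and is byte-stable", {
    cfg <- simulationConfig(numtFraction = 0, errorRate = 0,
                            enrichSlope = 0)
    refs <- simulateReference(cfg, seed = 2)
    meth <- rep(0.2, 166)
    rd <- simulateMedipReads(refs, meth, cfg, nFragments = 50000, seed = 1)
    expect_equal(length(rd$mate1), 50000)
    # slope 0: fragment starts uniform over their valid range; chi-square
    # against the exactly computed expectation
    grid <- tileWindows(cfg$mitoLength, 100)
    obs <- tabulate((rd$truth$pos - 1) %/% 100 + 1, nbins = 166)
    lens <- cfg$fragmentRange[1]:cfg$fragmentRange[2]
    expProb <- rep(0, 166)
    for (l in lens) {
        ns <- cfg$mitoLength - l + 1
        full <- (ns %/% 100)
        p <- c(rep(100 / ns, full), (ns - full * 100) / ns,
               rep(0, 166 - full - 1))
        expProb <- expProb + p / length(lens)
    }
    keep <- expProb > 0
    gof <- suppressWarnings(stats::chisq.test(obs[keep],
                                              p = expProb[keep] /
                                                  sum(expProb[keep])))
    expect_gt(gof$p.value, 0.001)

    # enrichment: methylation 0.2 vs 0.8 with zero base weight gives a
    # 1:4 fragment ratio (by midpoint window, the unit enrichment acts on)
    cfgE <- simulationConfig(numtFraction = 0, errorRate = 0,
                             baseWeight = 0)
    methE <- rep(0.5, 166); methE[50] <- 0.2; methE[120] <- 0.8
    rdE <- simulateMedipReads(refs, methE, cfgE, nFragments = 60000,
                              seed = 1)
    midW <- (rdE$truth$pos + rdE$truth$fragLen %/% 2 - 1) %/% 100 + 1
    n50 <- sum(midW == 50); n120 <- sum(midW == 120)
    phat <- n50 / (n50 + n120)
    expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / (n50 + n120)))

    # mates are the fragment ends (forward / reverse-complement)
    mito <- as.character(mitoSequence(refs$full))
    i <- 17
    s <- rd$truth$pos[i]; l <- rd$truth$fragLen[i]
    expect_identical(as.character(rd$mate1[[i]]), substr(mito, s, s + 49))
    expect_identical(as.character(rd$mate2[[i]]),
                     as.character(Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(
                             substr(mito, s + l - 50, s + l - 1))))[1])

    # same seed, byte-identical FASTQ
    rd2 <- simulateMedipReads(refs, meth, cfg, nFragments = 2000, seed = 9)
    rd3 <- simulateMedipReads(refs, meth, cfg, nFragments = 2000, seed = 9)
    f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
    writeFastqPair(rd2$mate1, rd2$mate2, f1, tempfile(fileext = ".fastq"),
                   constantQ = rd2$quality)
    writeFastqPair(rd3$mate1, rd3$mate2, f2, tempfile(fileext = ".fastq"),
                   constantQ = rd3$quality)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

    cfgBad <- simulationConfig()
    expect_error(simulationConfig(fragmentRange = c(220, 20000)))
})

test_that("window-count simulation matches the read-level marginal totals", {
    cfg <- simulationConfig(numtFraction = 0)
    meth <- rep(0.1, 166)
    meth[40:50] <- 0.8       # windows 3901-5000 strongly enriched
    cn <- simulateWindowCounts(meth, cfg, nFragments = 30000, seed = 5)
    expect_equal(sum(cn), 30000)
    expect_identical(cn, simulateWindowCounts(meth, cfg,
                                              nFragments = 30000, seed = 5))
    # enrichment shows up in the windows whose fragments' midpoints fall
    # wholly inside the enriched block
    expect_gt(mean(cn[40:46]), 3 * mean(cn[80:150]))
})

test_that("triage scoring against truth handles edge cases", {
    truth <- data.frame(read_id = paste0("r", 1:6),
                        origin = c(rep("mito", 4), "numt", "numt"),
                        chrom = "chrM", pos = 1L, fragLen = 250L)
    mk <- function(ids) new("RetainedReadSet",
                            fragments = data.frame(
                                read_id = ids,
                                pos = rep(1L, length(ids)),
                                span = rep(250L, length(ids))),
                            mitoName = "chrM")
    perfect <- evaluateTriage(truth, mk(paste0("r", 1:4)))
    expect_equal(perfect$precision, 1)
    expect_equal(perfect$recall, 1)
    mixed <- evaluateTriage(truth, mk(c("r1", "r5")))
    expect_equal(mixed$precision, 0.5)
    expect_equal(mixed$recall, 0.25)
    expect_warning(emptyEv <- evaluateTriage(truth, mk(character(0))),
                   "undefined")
    expect_true(is.na(emptyEv$precision))
    expect_equal(emptyEv$recall, 0)
    expect_error(evaluateTriage(truth, mk("zz")), "missing from truth")
})

test_that("planted-window classification separates signal from null", {
    cfg <- simulationConfig()
    st <- plantedWindowStatus(cfg)
    expect_equal(length(st), 166)
    g <- tileWindows(cfg$mitoLength, 100)
    s <- windowStarts(g)
    # informative windows: all midpoints inside a planted region
    expect_true(all(s[st == "informative"] %in%
                    c(2101, 2201, 2301, 16101, 16201, 16301)))
    # windows far from any planted region are null
    expect_true(all(st[s >= 5001 & s <= 12001] == "null"))
    # the geometrically unreachable tail windows are never null
    expect_true(all(st[s > cfg$mitoLength - cfg$fragmentRange[1] + 1] !=
                    "null"))
})
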