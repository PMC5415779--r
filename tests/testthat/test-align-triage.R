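test_that("toy aligner places verbatim reads and flags ambiguity", {
    refs <- tinyRefPair(seed = 7)
    rd <- readsFrom(refs$full, "chrM", c(1, 501, 1201))
    a <- toyAlign(rd, refs$full)
    expect_true(all(a$mapped))
    expect_true(all(a$unique))
    expect_identical(a$target, rep("chrM", 3))
    expect_equal(a$pos, c(1, 501, 1201))

    # reverse-complement read maps to the same locus on the minus strand
    rc <- Biostrings::reverseComplement(rd[2])
    arc <- toyAlign(rc, refs$full)
    expect_equal(arc$pos, 501)
    expect_identical(arc$strand, "-")

    # a sequence planted at two loci is mapped but not unique
    set.seed(8)
    dupSeg <- randomDna(50)
    chr <- paste0(randomDna(200), dupSeg, randomDna(200), dupSeg,
                  randomDna(200))
    ref2 <- referenceGenome(c(chr1 = chr, chrM = randomDna(400)))
    a2 <- toyAlign(Biostrings::DNAStringSet(c(q = dupSeg)), ref2)
    expect_true(a2$mapped)
    expect_false(a2$unique)
    expect_equal(a2$pos, 201)   # leftmost tie-break

    # unrelated random reads stay unmapped
    set.seed(1)
    rnd <- Biostrings::DNAStringSet(vapply(1:100, function(i) randomDna(50),
                                           ""))
    names(rnd) <- paste0("x", 1:100)
    expect_true(all(!toyAlign(rnd, refs$full)$mapped))

    expect_error(toyAlign(Biostrings::DNAStringSet(c(a = "ACGTACGT")),
                          refs$full, k = 15), "seed length")
})

test_that("triage passes implement select / exclude / confirm contracts", {
    aln <- data.frame(
        read_id = c("a", "a", "b", "b", "c", "c", "d", "d"),
        mate = rep(1:2, 4),
        target = c("chrM", "chrM", "chr1", "chr1", "chrM", "chrM",
                   "chrM", "chrM"),
        pos = c(10L, 200L, 5L, 100L, 50L, 260L, 70L, 300L),
        strand = "+", mapq = c(37L, 37L, 37L, 37L, 0L, 37L, 37L, 37L),
        mapped = TRUE,
        unique = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
        span = 50L, stringsAsFactors = FALSE)

    # unique-to-chrM pairs selected; chr1 and non-unique excluded
    expect_identical(pass1Select(aln, "chrM"), c("a", "d"))
    # "any" mode admits the half-unique pair
    expect_identical(pass1Select(aln, "chrM", pairMode = "any"),
                     c("a", "c", "d"))

    nuc <- data.frame(read_id = rep(c("a", "d"), each = 2), mate = 1:2,
                      target = c(NA, NA, "chr1", NA),
                      pos = c(NA, NA, 9L, NA), strand = NA,
                      mapq = 0L, mapped = c(FALSE, FALSE, TRUE, FALSE),
                      unique = FALSE, span = 50L, stringsAsFactors = FALSE)
    expect_identical(pass2Filter(c("a", "d"), nuc), "a")
    expect_identical(pass2Filter(character(0), nuc), character(0))
    expect_error(pass2Filter(c("a", "zz"), nuc), "missing")

    ret <- pass3Confirm("a", aln, "chrM")
    expect_s4_class(ret, "RetainedReadSet")
    fr <- retainedFragments(ret)
    expect_equal(fr$pos, 10)          # leftmost mate
    expect_equal(fr$span, 240)        # outer span 10..249
    # a read whose confirmation placement is non-unique is removed
    aln2 <- aln
    aln2$unique[aln2$read_id == "a"] <- FALSE
    expect_equal(nrow(retainedFragments(pass3Confirm("a", aln2, "chrM"))), 0)
})

test_that("full triage is monotone, deterministic and backend-agnostic", {
    refs <- tinyRefPair(mitoLen = 3000, nucLen = 4000, seed = 21)
    m1 <- readsFrom(refs$full, "chrM", seq(1, 2801, by = 200))
    m2 <- readsFrom(refs$full, "chrM", seq(101, 2901, by = 200))
    names(m2) <- names(m1)
    out <- runTriage(m1, m2, refs$full, refs$nuclear)
    v <- triageCounts(out$report)
    expect_true(all(diff(v) <= 0))
    expect_equal(unname(v["input"]), length(m1))
    expect_equal(nrow(retainedFragments(out$retained)), length(m1))

    out2 <- runTriage(m1, m2, refs$full, refs$nuclear)
    expect_identical(triageCounts(out2$report), v)
    expect_identical(retainedFragments(out2$retained),
                     retainedFragments(out$retained))

    # zero reads
    e <- Biostrings::DNAStringSet()
    z <- runTriage(e, NULL, refs$full, refs$nuclear)
    expect_true(all(triageCounts(z$report) == 0))
    expect_equal(nrow(retainedFragments(z$retained)), 0)

    # a "nuclear-only" reference still carrying chrM is rejected
    expect_error(runTriage(m1, m2, refs$full, refs$full), "contains")
})

test_that("SAM ingestion feeds the pass logic like the toy aligner", {
    refs <- tinyRefPair(mitoLen = 1500, nucLen = 1500, seed = 31)
    starts <- c(11, 401, 901)
    m1 <- readsFrom(refs$full, "chrM", starts)
    a <- toyAlign(m1, refs$full)

    # hand-written SAM mirroring those alignments plus an unmapped and a
    # MAPQ-0 record
    sam <- tempfile(fileext = ".sam")
    wd <- setNames(Biostrings::width(refSequences(refs$full)),
                   names(refSequences(refs$full)))
    mlen <- wd[["chrM"]]
    nlen <- wd[["chr1"]]
    lines <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:chr1\tLN:%d", nlen),
               sprintf("@SQ\tSN:chrM\tLN:%d", mlen),
               vapply(seq_along(starts), function(i) sprintf(
                   "%s\t0\tchrM\t%d\t37\t50M\t*\t0\t0\t%s\t*",
                   names(m1)[i], starts[i], as.character(m1[[i]])), ""),
               sprintf("un1\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", randomDna(50)),
               sprintf("mq0\t0\tchrM\t700\t0\t50M\t*\t0\t0\t%s\t*",
                       randomDna(50)))
    writeLines(lines, sam)
    b <- readAlignmentsSam(sam)
    expect_setequal(b$read_id, c(names(m1), "un1", "mq0"))
    expect_identical(pass1Select(b, "chrM"), sort(names(m1)))
    # backend equivalence on the shared reads: same selection, positions
    expect_identical(pass1Select(a, "chrM"), pass1Select(b, "chrM"))
    bm <- b[match(names(m1), b$read_id), ]
    am <- a[match(names(m1), a$read_id), ]
    expect_equal(bm$pos, am$pos)
    expect_false(b$unique[b$read_id == "mq0"])
    expect_false(b$mapped[b$read_id == "un1"])
})
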