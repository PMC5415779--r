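test_that("paired t matches the closed-form oracle", {
    x <- c(2, 3, 5); y <- c(1, 1, 2)          # d = (1, 2, 3)
    got <- pairedTWindow(x, y)
    orc <- oraclePairedT(x, y)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
    expect_equal(orc$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
    expect_equal(got$p, 0.0742, tolerance = 1e-3)
    expect_equal(got$delta, 2)

    # swapping the conditions negates delta, p unchanged
    swp <- pairedTWindow(y, x)
    expect_equal(swp$delta, -got$delta)
    expect_equal(swp$p, got$p)

    # constant differences are flagged, not forced to a p
    z <- pairedTWindow(c(4, 5, 6), c(1, 2, 3))
    expect_identical(z$code, "zero_variance")
    expect_true(is.na(z$p))
    expect_equal(z$delta, 3)

    expect_error(pairedTWindow(1, 2), "at least 2")
    expect_error(pairedTWindow(1:3, 1:2), "matched")

    set.seed(1)
    for (i in 1:200) {
        n <- sample(2:12, 1)
        a <- rnorm(n); b <- rnorm(n)
        if (sd(a - b) == 0) next
        expect_equal(pairedTWindow(a, b)$p, oraclePairedT(a, b)$p,
                     tolerance = 1e-10)
    }
})

test_that("mixed model detects planted tissue shifts and handles degeneracy", {
    set.seed(1)
    regions <- c("BA8", "BA9", "BA10", "ECX", "STG", "CER")
    d <- expand.grid(individual = 1:3, region = regions,
                     stringsAsFactors = FALSE)
    d$tissue <- ifelse(d$region == "CER", "cerebellum", "cortex")
    d$value <- rnorm(nrow(d), sd = 0.1) + ifelse(d$tissue == "cortex", 2, 0)
    r <- mixedModelWindow(d)
    expect_lt(r$p, 0.01)

    # transposed mode also yields a p for adding tissue
    rl <- mixedModelWindow(d, mode = "transposed")
    expect_true(is.finite(rl$p) && rl$p >= 0 && rl$p <= 1)
    expect_lt(rl$p, 0.05)

    rw <- mixedModelWindow(d, test = "Wald")
    expect_true(rw$p >= 0 && rw$p <= 1)

    # identical values: no tissue effect; singular fit is flagged
    d2 <- d; d2$value <- 1
    r2 <- mixedModelWindow(d2)
    expect_true(r2$code == "singular" || (!is.na(r2$p) && r2$p > 0.9))

    expect_error(mixedModelWindow(transform(d, tissue = "cortex")),
                 "two tissue")
    expect_error(mixedModelWindow(d[d$individual == 1, ]), "two individuals")
})

test_that("mixed-model and paired-t orderings agree across effect sizes", {
    # one cortical observation per individual, varying planted effects
    set.seed(1)
    nInd <- 6
    pm <- pt2 <- numeric(30)
    for (i in 1:30) {
        eff <- runif(1, 0, 1.2)
        cer <- rnorm(nInd, sd = 0.4)
        ctx <- cer + eff + rnorm(nInd, sd = 0.4)
        dd <- data.frame(value = c(ctx, cer),
                         tissue = rep(c("cortex", "cerebellum"),
                                      each = nInd),
                         individual = rep(1:nInd, 2),
                         region = rep(c("CTX", "CER"), each = nInd))
        pm[i] <- mixedModelWindow(dd)$p
        pt2[i] <- pairedTWindow(ctx, cer)$p
    }
    expect_gt(cor(rank(pm), rank(pt2)), 0.95)
})

test_that("Bonferroni threshold and nominal counting behave", {
    expect_equal(bonferroniThreshold(1), 0.05)
    expect_equal(bonferroniThreshold(71) * 71, 0.05)
    expect_error(bonferroniThreshold(0))

    res <- data.frame(start = rep(c(1, 101, 201), 2),
                      comparison = rep(c("A", "B"), each = 3),
                      p = c(0.01, 0.2, 0.03, 0.04, 0.2, NA),
                      analyzed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
    expect_equal(countNominal(res, level = "entries"), 3)
    expect_equal(countNominal(res, level = "windows"), 2)
    expect_gte(countNominal(res, level = "entries"),
               countNominal(res, level = "windows"))
    expect_equal(countNominal(res[0, ]), 0)
    # alpha = 1 counts every analyzed entry with a p
    expect_equal(countNominal(res, alpha = 1, level = "entries"), 5)
})

test_that("conserved-window logic is direction-aware and antitone", {
    res <- data.frame(
        start = rep(c(1, 101, 201, 301), 3),
        comparison = rep(c("A", "B", "C"), each = 4),
        p = c(0.01, 0.01, 0.2, 0.01,
              0.02, 0.01, 0.01, 0.01,
              0.03, 0.04, 0.01, 0.01),
        delta = c(1, -1, 2, -2,
                  2, -2, 1, -1,
                  3, -1, 1, 1),
        analyzed = TRUE)
    c1 <- conservedWindows(res, c("A", "B", "C"))
    expect_equal(c1$start, c(1, 101, 301))
    expect_identical(c1$direction, c("hyper", "hypo", "mixed"))
    # one comparison reduces to that comparison's nominal windows
    cA <- conservedWindows(res, "A")
    expect_equal(cA$start,
                 sort(res$start[res$comparison == "A" & res$p < 0.05]))
    # antitone in the subset
    expect_lte(nrow(conservedWindows(res, c("A", "B"))), nrow(cA))
    expect_lte(nrow(c1), nrow(conservedWindows(res, c("A", "B"))))
})

test_that("adjacent-run length counts consecutive grid windows", {
    grid <- tileWindows(1000, 100)
    expect_equal(longestAdjacentRun(integer(0), grid), 0)
    expect_equal(longestAdjacentRun(c(301), grid), 1)
    expect_equal(longestAdjacentRun(c(101, 201, 301, 501, 601), grid), 3)
    expect_equal(longestAdjacentRun(c(901, 1, 801), grid), 2)
    expect_error(longestAdjacentRun(c(150), grid), "grid")
})

test_that("direction concordance excludes zero deltas and calibrates at 50%", {
    a <- c(1, -2, 3, -4)
    expect_equal(directionConcordance(a, a), 100)
    expect_equal(directionConcordance(a, -a), 0)
    # zero deltas drop out of numerator and denominator
    expect_equal(directionConcordance(c(1, 0, -1), c(1, 5, -2)), 100)
    expect_warning(out <- directionConcordance(c(0, 0), c(1, 2)),
                   "undefined")
    expect_true(is.na(out))

    set.seed(1)
    x <- sample(c(-1, 1), 10000, replace = TRUE)
    y <- sample(c(-1, 1), 10000, replace = TRUE)
    ci <- 100 * (0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / 10000))
    got <- directionConcordance(x, y)
    expect_gt(got, ci[1]); expect_lt(got, ci[2])
})

test_that("per-window tests over a WindowExperiment respect the ND mask", {
    set.seed(4)
    counts <- matrix(rpois(20 * 6, 80), 20, 6,
                     dimnames = list(NULL,
                                     paste0(rep(c("BA8", "CER"), each = 3),
                                            "_ind", 1:3)))
    counts[5, ] <- 0L
    we <- makeTinyWE(counts, rep(c("BA8", "CER"), each = 3), rep(1:3, 2))
    res <- dmrPairedTest(we, "BA8")
    expect_equal(nrow(res), 20)
    expect_true(is.na(res$p[5]) && !res$analyzed[5])
    expect_true(all(!is.na(res$p[res$analyzed & res$code == "ok"])))
    # deltas match the assay means
    m <- SummarizedExperiment::assay(we, "log2rpkm")
    expect_equal(res$delta[1], mean(m[1, 1:3] - m[1, 4:6]))

    resM <- dmrMixedTest(we, cortexTissues = "BA8")
    expect_true(is.na(resM$p[5]))
    expect_true(all(resM$p[resM$analyzed] >= 0 &
                    resM$p[resM$analyzed] <= 1, na.rm = TRUE))
})
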