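test_that("exact signed-rank p-values for fully concordant samples", {
    # n = 5, all differences positive and distinct: W+ = 15, p = 2/32
    r5 <- wilcoxonSignedRankExact(c(5, 7, 9, 11, 13), c(1, 2, 3, 4, 5))
    expect_equal(r5$wPlus, 15)
    expect_equal(r5$nEff, 5L)
    expect_equal(r5$pTwoSided, 0.0625)
    # n = 10: p = 2/1024
    r10 <- wilcoxonSignedRankExact(11:20 + (1:10) * 0.1, 1:10)
    expect_equal(r10$pTwoSided, 2 / 1024)
})

test_that("degenerate and oversized samples are refused", {
    expect_error(wilcoxonSignedRankExact(rep(2, 4), rep(2, 4)), "degenerate")
    expect_error(wilcoxonSignedRankExact(1:16 + 0.5, 1:16), "n <= 15")
    expect_error(wilcoxonSignedRankExact(1:3, 1:2), "equal length")
    # zero differences are dropped before ranking
    r <- wilcoxonSignedRankExact(c(3, 3, 5, 7), c(3, 3, 1, 2))
    expect_equal(r$nEff, 2L)
})

test_that("negating all differences preserves p and reflects W+", {
    set.seed(12)
    for (i in 1:10) {
        n <- sample(3:12, 1)
        x <- rnorm(n); y <- rnorm(n)
        a <- wilcoxonSignedRankExact(x, y)
        b <- wilcoxonSignedRankExact(y, x)
        expect_equal(a$pTwoSided, b$pTwoSided)
        expect_equal(b$wPlus, a$nEff * (a$nEff + 1) / 2 - a$wPlus)
    }
})

test_that("evidence accumulates: all-same-sign p decreases with n", {
    ps <- vapply(3:12, function(n)
        wilcoxonSignedRankExact(seq_len(n) + 10, seq_len(n))$pTwoSided,
        numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("rank-convolution p equals the brute-force sign-enumeration oracle", {
    set.seed(23)
    for (i in 1:30) {
        n <- sample(3:8, 1)
        # half the cases contain ties in |differences|
        d <- if (i %% 2 == 0) round(rnorm(n) * 2) / 2 else rnorm(n)
        d[d == 0] <- 0.25
        y <- rnorm(n)
        x <- y + d
        expect_equal(wilcoxonSignedRankExact(x, y)$pTwoSided,
                     bruteWilcoxonP(x, y), tolerance = 1e-12)
    }
})

test_that("tie-free results agree with the reference exact implementation in stats", {
    set.seed(31)
    for (i in 1:10) {
        n <- sample(4:12, 1)
        x <- rnorm(n, 1); y <- rnorm(n)
        ours <- wilcoxonSignedRankExact(x, y)
        ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
        expect_equal(ours$pTwoSided, unname(ref$p.value), tolerance = 1e-12)
        expect_equal(ours$wPlus, unname(ref$statistic))
    }
})

test_that("mean and SEM follow the sample-SD definition", {
    expect_equal(meanSem(c(1, 2, 3)),
                 list(mean = 2, sem = 1 / sqrt(3), n = 3L),
                 tolerance = 1e-12)
    expect_equal(round(meanSem(c(1, 2, 3))$sem, 4), 0.5774)
    expect_equal(meanSem(rep(4.2, 6))$sem, 0)
    expect_error(meanSem(7), "two values")
})

test_that("the default cohort reproduces the calibrated diastasis summaries", {
    cohort <- generateCohort(defaultCohortParams())
    tt <- threeTimepointTable(cohort)
    dd <- tt[tt$timepoint == "mid_diastasis", ]
    endo <- dd[dd$measure == "endo", ]
    epi <- dd[dd$measure == "epi", ]
    expect_lt(abs(endo$meanDiff - 7.7), 1.4)
    expect_lt(abs(epi$meanDiff - 25.4), 2.3)
    # SEM within the a-priori 3-sigma sampling band of an SD-derived SEM
    # (sd of the sample SD is about sigma/sqrt(2(n-1)) at n = 10)
    expect_gt(endo$semDiff, 0.4); expect_lt(endo$semDiff, 2.4)
    expect_gt(epi$semDiff, 0.7); expect_lt(epi$semDiff, 4.0)
})

test_that("the three-timepoint table shows the healthy sign pattern", {
    cohort <- generateCohort(defaultCohortParams(seed = 2L))
    tt <- threeTimepointTable(cohort)
    # epicardial VSA exceeds ASA at all three timepoints in the mean
    expect_true(all(tt$meanDiff[tt$measure == "epi"] > 0))
    # endocardial VSA is below ASA at end systole, above at diastasis
    expect_lt(tt$meanDiff[tt$timepoint == "end_systole" & tt$measure == "endo"], 0)
    expect_gt(tt$meanDiff[tt$timepoint == "mid_diastasis" & tt$measure == "endo"], 0)
    # single-subject cohort: summary produced, SEM undefined
    c1 <- generateCohort(defaultCohortParams(nSubjects = 1L))
    t1 <- threeTimepointTable(c1)
    expect_equal(nrow(t1), 6L)
    expect_true(all(is.na(t1$semDiff)))
})
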