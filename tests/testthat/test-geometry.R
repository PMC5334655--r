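test_that("curves pass exactly through their landmarks and are periodic", {
    phases <- gridAlignedPhases()
    cases <- list(
        list(lm = ChamberLandmarks(14, 20, 16), chamber = "ASA"),
        list(lm = ChamberLandmarks(26, 12, 23.7), chamber = "VSA_endo"),
        list(lm = ChamberLandmarks(45, 38, 41.4), chamber = "VSA_epi"))
    for (cs in cases) {
        crv <- buildCurve(cs$lm, phases, nFrames = 21, chamber = cs$chamber)
        expect_equal(areaAt(crv, 0), cs$lm@aEd)
        expect_equal(areaAt(crv, 1), cs$lm@aEd)   # periodicity
        expect_equal(areaAt(crv, phases@tEs), cs$lm@aEs)
        expect_equal(areaAt(crv, phases@tDd), cs$lm@aDd)
        # closed form of the cosine interpolant at segment midpoints
        expect_equal(areaAt(crv, 0.20), (cs$lm@aEd + cs$lm@aEs) / 2)
        expect_equal(areaAt(crv, 0.55), (cs$lm@aEs + cs$lm@aDd) / 2)
        expect_equal(areaAt(crv, 0.95), (cs$lm@aDd + cs$lm@aEd) / 2)
        # plateau across diastasis
        expect_equal(areaAt(crv, 0.80), cs$lm@aDd)
    }
})

test_that("half-cosine segments are monotone between their landmarks", {
    phases <- defaultCyclePhases()
    crv <- buildCurve(ChamberLandmarks(14, 20, 16), phases, nFrames = 400)
    t <- crv@times
    segs <- list(c(0, phases@tEs), c(phases@tEs, phases@tDd),
                 c(phases@tDd, phases@tAk), c(phases@tAk, 1))
    dirs <- c(1, -1, 0, -1)   # rise, fall, plateau, fall for these landmarks
    for (k in seq_along(segs)) {
        inside <- t >= segs[[k]][1] & t <= segs[[k]][2]
        d <- diff(crv@areas[inside])
        if (dirs[k] > 0) expect_true(all(d >= 0))
        else if (dirs[k] < 0) expect_true(all(d <= 0))
        else expect_true(all(abs(d) < 1e-12))
    }
})

test_that("anchored endocardial curve meets the ASA exactly at the crossover and exceeds it after", {
    p <- defaultCohortParams()
    ph <- p@phases
    vCross <- AVHydraulics:::.evalLandmarks(ph@tCrossEndo, p@asa, ph)
    endoAtCross <- AVHydraulics:::.evalLandmarks(
        ph@tCrossEndo, p@vsaEndo, ph, vCross = vCross)
    expect_equal(endoAtCross, vCross)
    g <- populationGeometry(p, nFrames = 2001)
    t <- g@asa@times
    post <- t > ph@tCrossEndo & t < 1 + 1e-12
    expect_true(all(g@vsaEndo@areas[post] > g@asa@areas[post]))
    pre <- t > ph@tEs & t < ph@tCrossEndo
    expect_true(all(g@vsaEndo@areas[pre] < g@asa@areas[pre]))
})

test_that("infeasible anchors and invalid landmark orderings are rejected", {
    p <- defaultCohortParams()
    # end-systolic area not below the ASA crossover value
    expect_error(buildCurve(ChamberLandmarks(26, 19, 23.7), p@phases,
                            anchor = p@asa, chamber = "VSA_endo"),
                 "infeasible")
    expect_error(CyclePhases(0.6, 0.53, 0.7, 0.9), "ordering")
    expect_error(CyclePhases(0.3, 0.5, 0.7, 1.0), "inside")
    expect_error(ChamberLandmarks(-1, 20, 16), "positive")
})

test_that("area lookup interpolates linearly and respects the domain", {
    crv <- buildCurve(ChamberLandmarks(14, 20, 16), defaultCyclePhases(),
                      nFrames = 30)
    i <- 7L
    expect_identical(areaAt(crv, crv@times[i]), crv@areas[i])
    tm <- (crv@times[i] + crv@times[i + 1]) / 2
    expect_equal(areaAt(crv, tm), (crv@areas[i] + crv@areas[i + 1]) / 2)
    expect_equal(areaAt(crv, 1), areaAt(crv, 0))
    expect_error(areaAt(crv, -0.1), "within")
    expect_error(areaAt(crv, 1.1), "within")
})

test_that("subject generation is deterministic and degenerate without noise", {
    p <- smallParams(seed = 21L)
    s1 <- generateSubject(p, 3L)
    s2 <- generateSubject(p, 3L)
    expect_identical(s1, s2)
    expect_false(identical(generateSubject(p, 1L)@vsaEndo@areas,
                           generateSubject(p, 2L)@vsaEndo@areas))
    p0 <- smallParams(subjectSd = c(endo = 0, epi = 0))
    s <- generateSubject(p0, 5L)
    expect_equal(s@vsaEndo@areas,
                 buildCurve(p0@vsaEndo, p0@phases, p0@nFrames,
                            chamber = "VSA_endo")@areas)
    expect_equal(s@asa@areas,
                 buildCurve(p0@asa, p0@phases, p0@nFrames,
                            chamber = "ASA")@areas)
})

test_that("type invariants hold under noise for many generated subjects", {
    p <- defaultCohortParams(seed = 99L)
    for (i in seq_len(100L)) {
        s <- generateSubject(p, i)
        expect_true(all(s@vsaEpi@areas - s@vsaEndo@areas >= 0))
        expect_true(all(s@asa@areas > 0 & s@vsaEndo@areas > 0))
        expect_equal(s@asa@areas[1], s@asa@areas[length(s@asa@areas)])
    }
})

test_that("cohorts are reproducible and calibrated to the population landmarks", {
    p <- smallParams(nSubjects = 10L, seed = 4L)
    c1 <- generateCohort(p)
    c2 <- generateCohort(p)
    expect_identical(SummarizedExperiment::assay(c1, "vsa_endo"),
                     SummarizedExperiment::assay(c2, "vsa_endo"))
    # noiseless single subject: cohort values equal population arithmetic
    p1 <- defaultCohortParams(nSubjects = 1L,
                              subjectSd = c(endo = 0, epi = 0))
    c0 <- generateCohort(p1)
    g <- subjectGeometry(c0, 1L)
    expect_equal(areaAt(g@vsaEndo, p1@phases@tDd) - areaAt(g@asa, p1@phases@tDd),
                 23.7 - 16.0, tolerance = 1e-2)
    # cohort mean mid-diastasis endo difference near the configured 7.7 cm^2
    tt <- threeTimepointTable(c1)
    dd <- tt[tt$timepoint == "mid_diastasis" & tt$measure == "endo", ]
    expect_lt(abs(dd$meanDiff - 7.7), 3 * 4.4 / sqrt(10) + 0.1)
})
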