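test_that("pressure conversion uses the exact mmHg definition and round-trips", {
    expect_equal(round(mmHgToPa(10), 1), 1333.2)
    expect_equal(round(mmHgToPa(10)), 1333)
    expect_identical(mmHgToPa(0), 0)
    expect_lt(abs(mmHgToPa(760) - 101325), 0.5)
    for (p in c(-50, -1, 0.1, 7.5, 10, 120, 760))
        expect_equal(paToMmHg(mmHgToPa(p)), p, tolerance = 1e-12)
    expect_error(mmHgToPa(NA_real_), "finite")
})

test_that("net hydraulic force reproduces the landmark force values", {
    # 7.7 cm^2 difference at 10 mmHg -> 1.0 N; 25.4 cm^2 -> 3.4 N
    expect_equal(round(netHydraulicForce(23.7, 16.0, 10), 1), 1.0)
    expect_equal(round(netHydraulicForce(41.4, 16.0, 10), 1), 3.4)
    expect_equal(netHydraulicForce(17, 17, 8), 0)
    expect_equal(netHydraulicForce(20, 15, 10), 0.667, tolerance = 1e-3)
    expect_error(netHydraulicForce(0, 15, 10), "positive")
    expect_error(netHydraulicForce(20, -1, 10), "positive")
    expect_error(netHydraulicForce(20, 15, -2), ">= 0")
})

test_that("force is antisymmetric and linear in areas and pressures", {
    set.seed(8)
    for (i in 1:25) {
        vsa <- runif(1, 5, 50); asa <- runif(1, 5, 50)
        pLv <- runif(1, 0, 30); pLa <- runif(1, 0, 30)
        f <- netHydraulicForce(vsa, asa, pLv, pLa)
        # swapping the two (area, pressure) pairs negates the force
        expect_equal(netHydraulicForce(asa, vsa, pLa, pLv), -f)
        # doubling both pressures doubles the force
        expect_equal(netHydraulicForce(vsa, asa, 2 * pLv, 2 * pLa), 2 * f)
        # linearity in the ventricular area
        expect_equal(netHydraulicForce(2 * vsa, asa, pLv, pLa) - f,
                     mmHgToPa(pLv) * vsa * 1e-4)
        # equal-pressure reduction: F = P_pa * (vsa - asa) * 1e-4 exactly
        p <- runif(1, 0, 20)
        expect_equal(netHydraulicForce(vsa, asa, p, p),
                     mmHgToPa(p) * (vsa - asa) * 1e-4)
    }
})

test_that("diastolic force curves match the landmark arithmetic and sign pattern", {
    g <- populationGeometry()
    fc <- forceCurve(g, PressureModel(10))
    # at mid diastasis the endo force equals the landmark-difference force
    iDd <- which.min(abs(fc@times - g@phases@tDd))
    expect_equal(fc@forceEndo[iDd], netHydraulicForce(23.7, 16.0, 10),
                 tolerance = 1e-6)
    # endocardial force is negative just after end systole ...
    expect_lt(fc@forceEndo[2], 0)
    # ... while the epicardial force is positive for all of diastole
    expect_true(all(fc@forceEpi > 0))
})

test_that("the positive fraction of diastole is measured on the interpolated curve", {
    g <- populationGeometry()
    fc <- forceCurve(g)
    expect_equal(fractionDiastolePositive(fc, "endo"), 0.75, tolerance = 1e-3)
    expect_equal(fractionDiastolePositive(fc, "epi"), 1.0)
    # synthetic linear crossing: f rises from -1 to +1 over diastole -> 1/2
    lin <- new("ForceCurve", subjectId = "syn",
               times = seq(0.5, 1, length.out = 6),
               forceEndo = seq(-1, 1, length.out = 6),
               forceEpi = rep(-2, 6))
    expect_equal(fractionDiastolePositive(lin, "endo"), 0.5)
    expect_equal(fractionDiastolePositive(lin, "epi"), 0)
    # fraction is independent of grid resolution (zero located by interpolation)
    lin2 <- new("ForceCurve", subjectId = "syn",
                times = seq(0.5, 1, length.out = 101),
                forceEndo = seq(-1, 1, length.out = 101),
                forceEpi = rep(-2, 101))
    expect_equal(fractionDiastolePositive(lin2, "endo"), 0.5)
})
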