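test_that("static force follows the hydrostatic area-difference law", {
    rig <- PistonRig(aSmall = 10e-4, aLarge = 20e-4, h0 = 1.4,
                     rho = 1000, g = 9.81)
    expect_equal(staticNetForce(rig), 1000 * 9.81 * 1.4 * 10e-4)  # 13.73 N
    expect_equal(round(staticNetForce(rig), 2), 13.73)
    eq <- PistonRig(aSmall = 15e-4, aLarge = 15e-4)
    expect_equal(staticNetForce(eq), 0)
    rig2 <- PistonRig()
    expect_equal(staticNetForce(rig2, fExt = staticNetForce(rig2)), 0)
})

test_that("released piston moves spontaneously to the small-chamber stop and rests", {
    traj <- simulateRelease(PistonRig(), x0 = 0, dt = 1e-4, tEnd = 1)
    st <- trajectoryStates(traj)
    n <- nrow(st)
    expect_equal(st$x_m[n], PistonRig()@travel)
    expect_equal(st$v_m_s[n], 0)
    # monotone non-decreasing position from rest with no external force
    expect_true(all(diff(st$x_m) >= -1e-12))
})

test_that("an equal-area piston stays where it is released", {
    rig <- PistonRig(aSmall = 15e-4, aLarge = 15e-4)
    traj <- simulateRelease(rig, x0 = 0.01, dt = 1e-3, tEnd = 0.2)
    st <- trajectoryStates(traj)
    expect_true(all(abs(st$x_m - 0.01) < 1e-12))
    expect_true(all(st$v_m_s == 0))
})

test_that("column volume bookkeeping is exact and energy is not created", {
    rig <- PistonRig()
    traj <- simulateRelease(rig, x0 = 0, dt = 1e-4, tEnd = 1)
    st <- trajectoryStates(traj)
    n <- nrow(st)
    dA <- rig@aLarge - rig@aSmall
    # column volume decrease equals swept chamber volume difference
    expect_equal(rig@aColumn * (rig@h0 - st$h_m[n]), dA * (st$x_m[n] - 0),
                 tolerance = 1e-12)
    expect_equal(displacedVolume(traj), dA * st$x_m[n], tolerance = 1e-12)
    # dissipated + kinetic <= work done by the hydraulic force
    au <- pistonEnergyAudit(traj)
    expect_gt(au$workHydraulic, 0)
    expect_lte(au$kineticChange + au$dissipated,
               au$workHydraulic * (1 + 1e-6) + 1e-9)
})

test_that("the integrator converges as the step is refined", {
    rig <- PistonRig(damping = 200)   # slow enough not to reach the stop
    xEnd <- function(dt) {
        st <- trajectoryStates(simulateRelease(rig, 0, dt, tEnd = 0.05))
        st$x_m[nrow(st)]
    }
    expect_lt(abs(xEnd(2e-4) - xEnd(1e-4)), 1e-8)
})

test_that("direction law: motion is only toward the small chamber for random rigs", {
    set.seed(17)
    for (i in 1:8) {
        rig <- randomRig()
        traj <- simulateRelease(rig, x0 = 0, dt = 1e-4, tEnd = 0.3)
        st <- trajectoryStates(traj)
        expect_true(all(st$v_m_s >= -1e-12))
        expect_true(all(st$x_m >= -1e-12 & st$x_m <= rig@travel + 1e-12))
        expect_true(all(st$h_m >= 0))
    }
})

test_that("a dominant pull drives systole and release restores diastole with zero net volume", {
    rig <- PistonRig()
    # constant pull exceeding the maximum hydraulic force: piston reaches x = 0
    down <- simulateStroke(rig, function(t) 30, dt = 1e-4, tEnd = 1)
    stDown <- trajectoryStates(down)
    expect_equal(stDown$x_m[nrow(stDown)], 0)
    # pull exactly balancing the hydraulic term at rest: no motion
    hold <- simulateStroke(rig, function(t) staticNetForce(rig),
                           dt = 1e-3, tEnd = 0.1)
    stHold <- trajectoryStates(hold)
    expect_true(all(abs(stHold$x_m - rig@travel) < 1e-9))
    # full cycle: pull then release returns the piston to the diastolic stop
    cyc <- simulateStroke(rig, function(t) if (t < 0.5) 30 else 0,
                          dt = 1e-4, tEnd = 1.5)
    stCyc <- trajectoryStates(cyc)
    expect_equal(stCyc$x_m[nrow(stCyc)], rig@travel)
    expect_lt(abs(displacedVolume(cyc)), 1e-12)
})

test_that("invalid integration parameters raise domain errors", {
    rig <- PistonRig()
    expect_error(simulateRelease(rig, x0 = 0, dt = 0, tEnd = 1), "dt")
    expect_error(simulateRelease(rig, x0 = 0, dt = 1e-4, tEnd = -1), "tEnd")
    expect_error(simulateRelease(rig, x0 = 1, dt = 1e-4, tEnd = 1), "travel")
    expect_error(simulateStroke(rig, function(t) NaN, dt = 1e-3, tEnd = 0.01),
                 "non-finite")
})
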