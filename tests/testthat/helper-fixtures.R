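# Shared fixtures: small deterministic parameter sets used across test files.

# phases/grid chosen so several half-cosine segment midpoints fall exactly on
# grid points (grid step 0.05)
gridAlignedPhases <- function() CyclePhases(0.4, 0.5, 0.7, 0.9)

smallParams <- function(nSubjects = 4L, seed = 11L,
                        subjectSd = c(endo = 4.4, epi = 7.3)) {
    defaultCohortParams(nSubjects = nSubjects, seed = seed,
                        subjectSd = subjectSd)
}

# independent brute-force oracle: exact two-sided signed-rank p by explicit
# enumeration of all 2^n sign assignments of the raw differences
bruteWilcoxonP <- function(x, y) {
    d <- (x - y)
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    pLe <- mean(ws <= w + 1e-9)
    pGe <- mean(ws >= w - 1e-9)
    min(1, 2 * min(pLe, pGe))
}

randomRig <- function() {
    aSmall <- runif(1, 5e-4, 30e-4)
    aLarge <- aSmall + runif(1, 1e-4, 15e-4)
    travel <- runif(1, 0.01, 0.05)
    h0 <- runif(1, 0.5, 2)
    # standpipe large enough that the column is never exhausted
    aColumn <- 2 * (aLarge - aSmall) * travel / h0 + runif(1, 2e-4, 1e-3)
    PistonRig(aSmall = aSmall, aLarge = aLarge, aColumn = aColumn, h0 = h0,
              rho = runif(1, 800, 1200), g = 9.81,
              mPiston = runif(1, 0.1, 2),
              damping = sample(c(0, runif(1, 1, 100)), 1),
              travel = travel)
}
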