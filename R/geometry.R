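#' @include AllGenerics.R
NULL

## Half-cosine (cosine-eased) interpolation between two values.  Monotone
## between its endpoints, zero slope at both ends, closed-form midpoint
## (v0 + v1) / 2 -- which is why it is preferred over splines here.
.cosSeg <- function(t, t0, t1, v0, v1) {
    s <- (t - t0) / (t1 - t0)
    v0 + (v1 - v0) * (1 - cos(pi * s)) / 2
}

## Piecewise segment table for one chamber.  Without an anchor: systolic
## segment, single diastolic rise, diastasis plateau, atrial-kick return.
## With an anchor (VSA_endo crossover value vCross at tCrossEndo) the
## diastolic rise is split so the curve passes exactly through vCross.
.segmentTable <- function(lm, phases, vCross = NULL) {
    if (is.null(vCross)) {
        list(t0 = c(0, phases@tEs, phases@tDd, phases@tAk),
             t1 = c(phases@tEs, phases@tDd, phases@tAk, 1),
             v0 = c(lm@aEd, lm@aEs, lm@aDd, lm@aDd),
             v1 = c(lm@aEs, lm@aDd, lm@aDd, lm@aEd))
    } else {
        list(t0 = c(0, phases@tEs, phases@tCrossEndo, phases@tDd, phases@tAk),
             t1 = c(phases@tEs, phases@tCrossEndo, phases@tDd, phases@tAk, 1),
             v0 = c(lm@aEd, lm@aEs, vCross, lm@aDd, lm@aDd),
             v1 = c(lm@aEs, vCross, lm@aDd, lm@aDd, lm@aEd))
    }
}

## Continuous (grid-free) evaluation of the piecewise half-cosine curve.
.evalLandmarks <- function(t, lm, phases, vCross = NULL) {
    seg <- .segmentTable(lm, phases, vCross)
    idx <- findInterval(t, seg$t0)
    idx[idx < 1L] <- 1L
    .cosSeg(t, seg$t0[idx], seg$t1[idx], seg$v0[idx], seg$v1[idx])
}

#' Build a periodic area-time curve through chamber landmarks
#'
#' Constructs a piecewise half-cosine curve passing exactly through the end
#' diastolic area at t = 0 and t = 1, the end-systolic area at \code{tEs} and
#' the mid-diastasis area at \code{tDd}, with a plateau across diastasis and a
#' return (atrial-kick) segment from \code{tAk} back to end diastole.
#'
#' When \code{anchor} is supplied (the reference atrial landmarks, for
#' building the endocardial ventricular curve), the diastolic rise is split at
#' the crossover fraction \code{phases@tCrossEndo} so the curve equals the
#' reference ASA curve's value exactly there and exceeds it for all later
#' cycle fractions; infeasible anchors (end-systolic area not below the ASA
#' value at the crossover) raise an error.
#'
#' @param landmarks a [ChamberLandmarks-class].
#' @param phases a [CyclePhases-class].
#' @param nFrames number of samples, including both t = 0 and t = 1.
#' @param anchor optional [ChamberLandmarks-class] of the reference ASA curve.
#' @param chamber chamber label for the result.
#' @param subjectId identifier for the result.
#' @return An [AreaCurve-class].
#' @examples
#' phases <- defaultCyclePhases()
#' asa <- buildCurve(ChamberLandmarks(14, 20, 16), phases, chamber = "ASA")
#' endo <- buildCurve(ChamberLandmarks(26, 12, 23.7), phases,
#'                    anchor = ChamberLandmarks(14, 20, 16),
#'                    chamber = "VSA_endo")
#' @export
buildCurve <- function(landmarks, phases, nFrames = 30L, anchor = NULL,
                       chamber = "ASA", subjectId = "population") {
    validObject(landmarks)
    validObject(phases)
    nFrames <- as.integer(nFrames)
    if (nFrames < 8L) stop("invalid parameter: nFrames must be >= 8")
    vCross <- NULL
    if (!is.null(anchor)) {
        if (!is(anchor, "ChamberLandmarks"))
            stop("anchor must be a ChamberLandmarks object (the reference ASA)")
        vCross <- .evalLandmarks(phases@tCrossEndo, anchor, phases)
        if (landmarks@aEs >= vCross)
            stop(sprintf(paste0("anchor infeasible: end-systolic area (%.3f cm^2) ",
                                "is not below the reference ASA value %.3f cm^2 ",
                                "at the crossover"),
                         landmarks@aEs, vCross))
        if (landmarks@aDd <= vCross)
            stop(sprintf(paste0("anchor infeasible: mid-diastasis area (%.3f cm^2) ",
                                "must exceed the crossover value %.3f cm^2"),
                         landmarks@aDd, vCross))
    }
    times <- seq(0, 1, length.out = nFrames)
    areas <- .evalLandmarks(times, landmarks, phases, vCross)
    areas[nFrames] <- areas[1L]   # guard periodicity against fp noise
    if (!is.null(anchor)) {
        ref <- .evalLandmarks(times, anchor, phases)
        post <- times > phases@tCrossEndo + 1e-12 & times < 1 + 1e-12
        if (any(areas[post] <= ref[post]))
            stop("anchor infeasible: curve does not exceed the reference ASA after the crossover")
    }
    AreaCurve(subjectId, chamber, times, areas)
}

#' @rdname areaAt
setMethod("areaAt", "AreaCurve", function(x, t, ...) {
    if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
        stop("t must lie within [0, 1]")
    approx(x@times, x@areas, xout = t, method = "linear", ties = "ordered")$y
})

## Deterministic per-subject stream: a distinct, reproducible seed derived
## from (cohort seed, subject index), kept below 2^31.
.subjectSeed <- function(seed, subjectIndex) {
    (abs(as.numeric(seed)) + 62791 * as.numeric(subjectIndex)) %% 2147483629
}

.shiftLandmarks <- function(lm, shift) {
    ChamberLandmarks(lm@aEd + shift, lm@aEs + shift, lm@aDd + shift)
}

.buildSubject <- function(params, endoShift, epiShift, subjectId) {
    SubjectGeometry(
        asa = buildCurve(params@asa, params@phases, params@nFrames,
                         chamber = "ASA", subjectId = subjectId),
        vsaEndo = buildCurve(.shiftLandmarks(params@vsaEndo, endoShift),
                             params@phases, params@nFrames,
                             chamber = "VSA_endo", subjectId = subjectId),
        vsaEpi = buildCurve(.shiftLandmarks(params@vsaEpi, epiShift),
                            params@phases, params@nFrames,
                            chamber = "VSA_epi", subjectId = subjectId),
        phases = params@phases)
}

#' Generate one synthetic subject
#'
#' Draws a single standard-normal subject effect and shifts the ventricular
#' landmark sets by \code{subjectSdEndo} and \code{subjectSdEpi} times that
#' effect (atrial landmarks are the population values).  Draws violating the
#' type invariants (positivity, epicardium enclosing endocardium) are redrawn,
#' up to 100 attempts.  Deterministic given \code{(seed, subjectIndex)}.
#'
#' @param params a [CohortParams-class].
#' @param subjectIndex 1-based subject index.
#' @return A [SubjectGeometry-class].
#' @export
generateSubject <- function(params, subjectIndex) {
    validObject(params)
    subjectIndex <- as.integer(subjectIndex)
    if (subjectIndex < 1L) stop("subjectIndex must be >= 1")
    id <- sprintf("S%02d", subjectIndex)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(.subjectSeed(params@seed, subjectIndex))
    for (attempt in seq_len(100L)) {
        z <- rnorm(1L)
        geom <- tryCatch(
            .buildSubject(params, params@subjectSdEndo * z,
                          params@subjectSdEpi * z, id),
            error = function(e) NULL)
        if (!is.null(geom)) return(geom)
    }
    stop("generation error: no invariant-satisfying draw within 100 attempts")
}

#' Generate a synthetic cohort of area-time curves
#'
#' Generates \code{params@nSubjects} independent subjects (see
#' [generateSubject()]) and assembles them into an [AVAreaCohort-class].
#' Bit-identical output for identical parameters.
#'
#' @param params a [CohortParams-class].
#' @return An [AVAreaCohort-class].
#' @examples
#' cohort <- generateCohort(defaultCohortParams(nSubjects = 4, seed = 7))
#' cohort
#' @export
generateCohort <- function(params) {
    validObject(params)
    subs <- lapply(seq_len(params@nSubjects),
                   function(i) generateSubject(params, i))
    ids <- vapply(subs, function(s) s@asa@subjectId, character(1))
    times <- subs[[1L]]@asa@times
    mk <- function(slot)
        vapply(subs, function(s) methods::slot(s, slot)@areas,
               numeric(length(times)))
    se <- SummarizedExperiment(
        assays = list(asa = mk("asa"), vsa_endo = mk("vsaEndo"),
                      vsa_epi = mk("vsaEpi")),
        rowData = DataFrame(time_frac = times),
        colData = DataFrame(subject_id = ids, row.names = ids),
        metadata = list(phases = params@phases, params = params))
    new("AVAreaCohort", se)
}

#' Population-mean geometry under the generator defaults
#'
#' Builds the three population-mean curves (no between-subject noise) with
#' the endocardial ventricular curve anchored at the ASA crossover, matching
#' the cohort-level temporal structure: the mean VSA_endo equals the mean ASA
#' exactly at \code{tCrossEndo} and exceeds it for the rest of the cycle.
#'
#' @param params a [CohortParams-class].
#' @param nFrames grid resolution for the mean curves; finer than the
#'   per-subject cine grid by default so diastolic summary measures are
#'   effectively grid-free.
#' @return A [SubjectGeometry-class].
#' @export
populationGeometry <- function(params = defaultCohortParams(),
                               nFrames = 1001L) {
    validObject(params)
    SubjectGeometry(
        asa = buildCurve(params@asa, params@phases, nFrames,
                         chamber = "ASA"),
        vsaEndo = buildCurve(params@vsaEndo, params@phases, nFrames,
                             anchor = params@asa, chamber = "VSA_endo"),
        vsaEpi = buildCurve(params@vsaEpi, params@phases, nFrames,
                            chamber = "VSA_epi"),
        phases = params@phases)
}

#' @rdname subjectGeometry
setMethod("subjectGeometry", "AVAreaCohort", function(x, i, ...) {
    if (is.character(i)) i <- match(i, colData(x)$subject_id)
    if (is.na(i) || i < 1L || i > ncol(x)) stop("subject not found in cohort")
    times <- rowData(x)$time_frac
    id <- colData(x)$subject_id[i]
    phases <- metadata(x)$phases
    SubjectGeometry(
        asa = AreaCurve(id, "ASA", times, assay(x, "asa")[, i]),
        vsaEndo = AreaCurve(id, "VSA_endo", times, assay(x, "vsa_endo")[, i]),
        vsaEpi = AreaCurve(id, "VSA_epi", times, assay(x, "vsa_epi")[, i]),
        phases = phases)
})

#' @rdname cyclePhases
#' @export
setMethod("cyclePhases", "AVAreaCohort", function(x) metadata(x)$phases)

#' @rdname cyclePhases
#' @export
setMethod("cyclePhases", "SubjectGeometry", function(x) x@phases)

## Interpolated assay values at one cycle fraction, across subjects.
.assayAt <- function(cohort, name, t) {
    times <- rowData(cohort)$time_frac
    m <- assay(cohort, name)
    apply(m, 2L, function(a)
        approx(times, a, xout = t, method = "linear", ties = "ordered")$y)
}
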