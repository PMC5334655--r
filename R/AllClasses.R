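#' @import methods
#' @importFrom stats approx rnorm sd
#' @importFrom utils head tail read.csv write.csv
NULL

.CHAMBERS <- c("ASA", "VSA_endo", "VSA_epi")

.scalarOk <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## ---------------------------------------------------------------------------
## CyclePhases
## ---------------------------------------------------------------------------

#' Landmark timing of the normalized cardiac cycle
#'
#' Phase landmarks expressed as fractions of the cardiac cycle, with t = 0 at
#' end diastole (R-wave) and t = 1 at the next end diastole.  Diastole is the
#' interval from end systole (\code{tEs}) to 1.
#'
#' @slot tEs fraction of the cycle at end systole.
#' @slot tCrossEndo fraction at which the endocardial ventricular short-axis
#'   area crosses above the atrial short-axis area.
#' @slot tDd fraction at mid diastasis.
#' @slot tAk fraction at the onset of the atrial kick.
#'
#' @seealso [CyclePhases()], [defaultCyclePhases()]
#' @name CyclePhases-class
#' @exportClass CyclePhases
setClass("CyclePhases",
    slots = c(tEs = "numeric", tCrossEndo = "numeric",
              tDd = "numeric", tAk = "numeric"))

setValidity("CyclePhases", function(object) {
    v <- c(object@tEs, object@tCrossEndo, object@tDd, object@tAk)
    if (!all(vapply(v, .scalarOk, logical(1))))
        return("all phase landmarks must be finite scalars")
    if (any(v <= 0) || any(v >= 1))
        return("all phase landmarks must lie strictly inside (0, 1)")
    if (!(object@tEs < object@tCrossEndo && object@tCrossEndo < object@tDd &&
          object@tDd < object@tAk))
        return("phase ordering violated: need tEs < tCrossEndo < tDd < tAk")
    TRUE
})

#' @rdname CyclePhases-class
#' @param tEs,tCrossEndo,tDd,tAk cycle fractions, see slots.
#' @return A \code{CyclePhases} object.
#' @export
CyclePhases <- function(tEs, tCrossEndo, tDd, tAk) {
    new("CyclePhases", tEs = as.numeric(tEs), tCrossEndo = as.numeric(tCrossEndo),
        tDd = as.numeric(tDd), tAk = as.numeric(tAk))
}

#' @rdname CyclePhases-class
#' @details
#' \code{defaultCyclePhases()} places the endocardial crossover at 53\% of the
#' cycle and derives end systole from the requirement that the crossover-to-end
#' interval spans 75\% of diastole, i.e. \eqn{t_{es} = 1 - 0.47/0.75}.  Mid
#' diastasis (0.70) and atrial-kick onset (0.90) are plausible defaults that
#' produce a visible diastasis plateau.
#' @export
defaultCyclePhases <- function() {
    CyclePhases(tEs = 1 - 0.47 / 0.75, tCrossEndo = 0.53, tDd = 0.70, tAk = 0.90)
}

## ---------------------------------------------------------------------------
## ChamberLandmarks
## ---------------------------------------------------------------------------

#' Chamber short-axis areas at the three cardinal timepoints
#'
#' @slot aEd area (cm^2) at end diastole.
#' @slot aEs area (cm^2) at end systole.
#' @slot aDd area (cm^2) at mid diastasis.
#'
#' @name ChamberLandmarks-class
#' @exportClass ChamberLandmarks
setClass("ChamberLandmarks",
    slots = c(aEd = "numeric", aEs = "numeric", aDd = "numeric"))

setValidity("ChamberLandmarks", function(object) {
    v <- c(object@aEd, object@aEs, object@aDd)
    if (!all(vapply(v, .scalarOk, logical(1))))
        return("landmark areas must be finite scalars")
    if (any(v <= 0))
        return("landmark areas must be strictly positive (cm^2)")
    TRUE
})

#' @rdname ChamberLandmarks-class
#' @param aEd,aEs,aDd areas in cm^2.
#' @return A \code{ChamberLandmarks} object.
#' @export
ChamberLandmarks <- function(aEd, aEs, aDd) {
    new("ChamberLandmarks", aEd = as.numeric(aEd), aEs = as.numeric(aEs),
        aDd = as.numeric(aDd))
}

## ---------------------------------------------------------------------------
## AreaCurve
## ---------------------------------------------------------------------------

#' One chamber's short-axis area over the normalized cardiac cycle
#'
#' A periodic area-time curve sampled on a strictly increasing time grid
#' spanning exactly one cycle (first time 0, last time 1, equal areas at the
#' two ends).
#'
#' @slot subjectId character identifier.
#' @slot chamber one of \code{"ASA"}, \code{"VSA_endo"}, \code{"VSA_epi"}.
#' @slot times cycle fractions in \code{[0, 1]}.
#' @slot areas areas in cm^2, same length as \code{times}.
#'
#' @name AreaCurve-class
#' @exportClass AreaCurve
setClass("AreaCurve",
    slots = c(subjectId = "character", chamber = "character",
              times = "numeric", areas = "numeric"))

setValidity("AreaCurve", function(object) {
    t <- object@times; a <- object@areas
    if (length(object@chamber) != 1L || !object@chamber %in% .CHAMBERS)
        return(sprintf("chamber must be one of %s",
                       paste(.CHAMBERS, collapse = ", ")))
    if (length(t) < 2L || length(t) != length(a))
        return("times and areas must be equal-length vectors (>= 2 samples)")
    if (any(!is.finite(t)) || any(!is.finite(a)))
        return("times and areas must be finite")
    if (t[1L] != 0 || t[length(t)] != 1)
        return("time grid must start at 0 and end at 1")
    if (any(diff(t) <= 0))
        return("times must be strictly increasing")
    if (any(a <= 0))
        return("areas must be strictly positive")
    if (abs(a[1L] - a[length(a)]) > 1e-9)
        return("curve must be periodic: area at t = 0 must equal area at t = 1")
    TRUE
})

#' @rdname AreaCurve-class
#' @param subjectId,chamber,times,areas see slots.
#' @return An \code{AreaCurve} object.
#' @export
AreaCurve <- function(subjectId, chamber, times, areas) {
    new("AreaCurve", subjectId = as.character(subjectId),
        chamber = as.character(chamber),
        times = as.numeric(times), areas = as.numeric(areas))
}

## ---------------------------------------------------------------------------
## SubjectGeometry
## ---------------------------------------------------------------------------

#' A subject's three area curves plus cycle-phase landmarks
#'
#' Bundles the atrial (\code{asa}), endocardial ventricular (\code{vsaEndo})
#' and epicardial ventricular (\code{vsaEpi}) short-axis area curves of one
#' subject, all sampled on the same time grid, together with the cycle phases.
#' The epicardial curve must dominate the endocardial curve at every sample
#' (the epicardium encloses the endocardium plus wall).
#'
#' @slot asa,vsaEndo,vsaEpi [AreaCurve-class] objects on a shared grid.
#' @slot phases a [CyclePhases-class] object.
#'
#' @name SubjectGeometry-class
#' @exportClass SubjectGeometry
setClass("SubjectGeometry",
    slots = c(asa = "AreaCurve", vsaEndo = "AreaCurve",
              vsaEpi = "AreaCurve", phases = "CyclePhases"))

setValidity("SubjectGeometry", function(object) {
    if (object@asa@chamber != "ASA" ||
        object@vsaEndo@chamber != "VSA_endo" ||
        object@vsaEpi@chamber != "VSA_epi")
        return("curves must carry chambers ASA / VSA_endo / VSA_epi")
    if (!identical(object@asa@times, object@vsaEndo@times) ||
        !identical(object@asa@times, object@vsaEpi@times))
        return("all three curves must share the same time grid")
    if (any(object@vsaEpi@areas - object@vsaEndo@areas < -1e-6))
        return("VSA_epi must be >= VSA_endo at every sample")
    TRUE
})

#' @rdname SubjectGeometry-class
#' @param asa,vsaEndo,vsaEpi,phases see slots.
#' @return A \code{SubjectGeometry} object.
#' @export
SubjectGeometry <- function(asa, vsaEndo, vsaEpi, phases) {
    new("SubjectGeometry", asa = asa, vsaEndo = vsaEndo, vsaEpi = vsaEpi,
        phases = phases)
}

## ---------------------------------------------------------------------------
## CohortParams
## ---------------------------------------------------------------------------

#' Parameters of the synthetic cohort generator
#'
#' Population landmark areas for the three chambers, cycle phases, the
#' between-subject standard deviations of the shared ventricular random
#' effect, the grid resolution and the seed.  The landmark sign pattern of
#' the healthy cohort is enforced: at end systole the endocardial ventricular
#' area is below the atrial area while the epicardial one is above it, and at
#' mid diastasis both ventricular areas exceed the atrial area.
#'
#' @slot nSubjects number of subjects (>= 1).
#' @slot asa,vsaEndo,vsaEpi population [ChamberLandmarks-class] per chamber.
#' @slot phases a [CyclePhases-class] object.
#' @slot subjectSdEndo,subjectSdEpi between-subject SD (cm^2) applied to the
#'   endocardial / epicardial ventricular landmarks through one shared
#'   standard-normal subject effect.
#' @slot nFrames samples per cycle (>= 8).
#' @slot seed integer random-number seed.
#'
#' @name CohortParams-class
#' @exportClass CohortParams
setClass("CohortParams",
    slots = c(nSubjects = "integer",
              asa = "ChamberLandmarks", vsaEndo = "ChamberLandmarks",
              vsaEpi = "ChamberLandmarks", phases = "CyclePhases",
              subjectSdEndo = "numeric", subjectSdEpi = "numeric",
              nFrames = "integer", seed = "integer"))

setValidity("CohortParams", function(object) {
    if (object@nSubjects < 1L) return("nSubjects must be >= 1")
    if (object@nFrames < 8L) return("nFrames must be >= 8")
    if (!.scalarOk(object@subjectSdEndo) || !.scalarOk(object@subjectSdEpi) ||
        object@subjectSdEndo < 0 || object@subjectSdEpi < 0)
        return("subject SDs must be finite and >= 0")
    if (!(object@vsaEndo@aEs < object@asa@aEs))
        return("population landmarks must satisfy VSA_endo a_es < ASA a_es")
    if (!(object@vsaEpi@aEs > object@asa@aEs))
        return("population landmarks must satisfy VSA_epi a_es > ASA a_es")
    if (!(object@vsaEndo@aDd > object@asa@aDd))
        return("population landmarks must satisfy VSA_endo a_dd > ASA a_dd")
    if (!(object@vsaEpi@aDd > object@asa@aDd))
        return("population landmarks must satisfy VSA_epi a_dd > ASA a_dd")
    TRUE
})

#' @rdname CohortParams-class
#' @param nSubjects,asa,vsaEndo,vsaEpi,phases,nFrames,seed see slots.
#' @param subjectSd numeric of length 2 (or named \code{c(endo =, epi =)}),
#'   between-subject SDs in cm^2.
#' @return A \code{CohortParams} object.
#' @export
CohortParams <- function(nSubjects, asa, vsaEndo, vsaEpi,
                         phases = defaultCyclePhases(),
                         subjectSd = c(endo = 0, epi = 0),
                         nFrames = 30L, seed = 1L) {
    if (!is.null(names(subjectSd)) && all(c("endo", "epi") %in% names(subjectSd)))
        subjectSd <- subjectSd[c("endo", "epi")]
    new("CohortParams", nSubjects = as.integer(nSubjects),
        asa = asa, vsaEndo = vsaEndo, vsaEpi = vsaEpi, phases = phases,
        subjectSdEndo = as.numeric(subjectSd[[1L]]),
        subjectSdEpi = as.numeric(subjectSd[[2L]]),
        nFrames = as.integer(nFrames), seed = as.integer(seed))
}

#' Default cohort parameters of the healthy-volunteer emulation
#'
#' Population landmarks (cm^2): ASA 14.0 / 20.0 / 16.0, VSA_endo 26.0 / 12.0 /
#' 23.7 and VSA_epi 45.0 / 38.0 / 41.4 at end diastole / end systole / mid
#' diastasis.  The mid-diastasis ventricular-minus-atrial differences are thus
#' 7.7 cm^2 (endocardial) and 25.4 cm^2 (epicardial); absolute levels are free
#' parameters since only differences enter the force model.  Between-subject
#' SDs default to 4.4 and 7.3 cm^2 (SEM x sqrt(10) for printed SEMs of 1.4 and
#' 2.3 at n = 10).
#'
#' @param nSubjects cohort size, default 10.
#' @param nFrames samples per cycle, default 30 (typical cine CMR).
#' @param seed integer seed, default 1.
#' @param subjectSd length-2 between-subject SDs (cm^2), endo then epi.
#' @return A [CohortParams-class] object.
#' @examples
#' params <- defaultCohortParams()
#' params
#' @export
defaultCohortParams <- function(nSubjects = 10L, nFrames = 30L, seed = 1L,
                                subjectSd = c(endo = 4.4, epi = 7.3)) {
    CohortParams(nSubjects = nSubjects,
                 asa = ChamberLandmarks(14.0, 20.0, 16.0),
                 vsaEndo = ChamberLandmarks(26.0, 12.0, 23.7),
                 vsaEpi = ChamberLandmarks(45.0, 38.0, 41.4),
                 phases = defaultCyclePhases(),
                 subjectSd = subjectSd, nFrames = nFrames, seed = seed)
}

## ---------------------------------------------------------------------------
## AVAreaCohort
## ---------------------------------------------------------------------------

#' Cohort of area-time curves as a SummarizedExperiment
#'
#' Container for a cohort of subjects' short-axis area curves.  Rows are
#' cardiac-cycle frames (rowData column \code{time_frac}), columns are
#' subjects (colData column \code{subject_id}) and the three assays
#' \code{asa}, \code{vsa_endo} and \code{vsa_epi} hold areas in cm^2.
#' Cycle phases (and, for generated cohorts, the generator parameters) live
#' in \code{metadata()}.
#'
#' @name AVAreaCohort-class
#' @exportClass AVAreaCohort
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
setClass("AVAreaCohort", contains = "SummarizedExperiment")

setValidity("AVAreaCohort", function(object) {
    an <- assayNames(object)
    if (!all(c("asa", "vsa_endo", "vsa_epi") %in% an))
        return("assays 'asa', 'vsa_endo' and 'vsa_epi' are required")
    if (!"time_frac" %in% colnames(rowData(object)))
        return("rowData must contain 'time_frac'")
    if (!"subject_id" %in% colnames(colData(object)))
        return("colData must contain 'subject_id'")
    if (nrow(object) > 0L) {
        t <- rowData(object)$time_frac
        if (t[1L] != 0 || t[length(t)] != 1 || any(diff(t) <= 0))
            return("time_frac must increase strictly from 0 to 1")
        if (ncol(object) > 0L) {
            for (a in c("asa", "vsa_endo", "vsa_epi"))
                if (any(assay(object, a) <= 0))
                    return(sprintf("assay '%s' must be strictly positive", a))
            if (any(assay(object, "vsa_epi") - assay(object, "vsa_endo") < -1e-6))
                return("vsa_epi must be >= vsa_endo everywhere")
        }
    }
    if (!is(metadata(object)$phases, "CyclePhases"))
        return("metadata must carry a CyclePhases object under 'phases'")
    TRUE
})

## ---------------------------------------------------------------------------
## PressureModel
## ---------------------------------------------------------------------------

#' Diastolic chamber pressures
#'
#' With the mitral valve open, the left atrium and ventricle are hydraulically
#' one chamber during diastasis, so the default model assumes equal pressures
#' (\code{equalPressure = TRUE}); 10 mmHg is the mean diastolic LV pressure of
#' normal individuals.
#'
#' @slot pLa left-atrial pressure, mmHg.
#' @slot pLv left-ventricular pressure, mmHg.
#' @slot equalPressure logical; if TRUE the two pressures must be equal.
#'
#' @name PressureModel-class
#' @exportClass PressureModel
setClass("PressureModel",
    slots = c(pLa = "numeric", pLv = "numeric", equalPressure = "logical"))

setValidity("PressureModel", function(object) {
    if (!.scalarOk(object@pLa) || !.scalarOk(object@pLv))
        return("pressures must be finite scalars")
    if (object@pLa < 0 || object@pLv < 0)
        return("pressures must be >= 0 mmHg")
    if (isTRUE(object@equalPressure) && object@pLa != object@pLv)
        return("equal-pressure mode requires pLa == pLv")
    TRUE
})

#' @rdname PressureModel-class
#' @param pLv,pLa pressures in mmHg (default 10).
#' @param equalPressure logical (default TRUE).
#' @return A \code{PressureModel} object.
#' @export
PressureModel <- function(pLv = 10, pLa = pLv, equalPressure = (pLa == pLv)) {
    new("PressureModel", pLa = as.numeric(pLa), pLv = as.numeric(pLv),
        equalPressure = isTRUE(equalPressure))
}

## ---------------------------------------------------------------------------
## ForceCurve
## ---------------------------------------------------------------------------

#' Net hydraulic force over diastole
#'
#' Longitudinal (apex-to-base) net hydraulic force in newtons over the
#' diastolic interval, for the endocardial and epicardial ventricular area
#' definitions.  Positive force points toward the base (aids filling).
#'
#' @slot subjectId character identifier.
#' @slot times cycle fractions within diastole, strictly increasing.
#' @slot forceEndo,forceEpi forces in N, same length as \code{times}.
#'
#' @name ForceCurve-class
#' @exportClass ForceCurve
setClass("ForceCurve",
    slots = c(subjectId = "character", times = "numeric",
              forceEndo = "numeric", forceEpi = "numeric"))

setValidity("ForceCurve", function(object) {
    t <- object@times
    if (length(t) < 2L) return("a force curve needs at least two samples")
    if (any(diff(t) <= 0)) return("times must be strictly increasing")
    if (length(object@forceEndo) != length(t) ||
        length(object@forceEpi) != length(t))
        return("force arrays must match the time grid length")
    if (any(!is.finite(object@forceEndo)) || any(!is.finite(object@forceEpi)))
        return("forces must be finite")
    TRUE
})

## ---------------------------------------------------------------------------
## DrivingForceEstimate
## ---------------------------------------------------------------------------

#' Peak driving force of LV filling from force-per-mass and inertial load
#'
#' @slot fPerMass force per unit mass, mN/g.
#' @slot lvMass left-ventricular mass, g.
#' @slot extraMin,extraMax extra inertial mass (blood + great-vessel roots), g.
#' @slot loadMin,loadMax total inertial load range, g.
#' @slot forceMin,forceMax resulting peak-force range, N.
#'
#' @name DrivingForceEstimate-class
#' @exportClass DrivingForceEstimate
setClass("DrivingForceEstimate",
    slots = c(fPerMass = "numeric", lvMass = "numeric",
              extraMin = "numeric", extraMax = "numeric",
              loadMin = "numeric", loadMax = "numeric",
              forceMin = "numeric", forceMax = "numeric"))

setValidity("DrivingForceEstimate", function(object) {
    v <- c(object@fPerMass, object@lvMass, object@extraMin, object@extraMax,
           object@loadMin, object@loadMax, object@forceMin, object@forceMax)
    if (!all(vapply(v, .scalarOk, logical(1))) || any(v < 0))
        return("all quantities must be finite and >= 0")
    if (abs(object@loadMin - (object@lvMass + object@extraMin)) > 1e-9 ||
        abs(object@loadMax - (object@lvMass + object@extraMax)) > 1e-9)
        return("load range must equal lvMass + extra range")
    if (object@loadMin > object@loadMax) return("loadMin must be <= loadMax")
    if (object@forceMin > object@forceMax) return("forceMin must be <= forceMax")
    TRUE
})

## ---------------------------------------------------------------------------
## PistonRig / PistonTrajectory
## ---------------------------------------------------------------------------

#' Geometry and lumped parameters of the hollow-piston analog rig
#'
#' A hollow piston with two end areas slides in a two-chamber housing
#' pressurized by a water column; the small end plays the atrial short-axis
#' area and the large end the ventricular one.  Units are SI throughout.
#'
#' @slot aSmall,aLarge piston end areas, m^2 (\code{aSmall <= aLarge}).
#' @slot aColumn standpipe cross-section, m^2.
#' @slot h0 initial water-column height above the piston axis, m.
#' @slot rho fluid density, kg/m^3.
#' @slot g gravitational acceleration, m/s^2.
#' @slot mPiston piston mass, kg.
#' @slot damping lumped viscous losses (conduit + seals), N s/m.
#' @slot travel maximum displacement between the stops, m.
#'
#' @name PistonRig-class
#' @exportClass PistonRig
setClass("PistonRig",
    slots = c(aSmall = "numeric", aLarge = "numeric", aColumn = "numeric",
              h0 = "numeric", rho = "numeric", g = "numeric",
              mPiston = "numeric", damping = "numeric", travel = "numeric"))

setValidity("PistonRig", function(object) {
    v <- c(object@aSmall, object@aLarge, object@aColumn, object@h0,
           object@rho, object@g, object@mPiston, object@damping, object@travel)
    if (!all(vapply(v, .scalarOk, logical(1))))
        return("all rig parameters must be finite scalars")
    if (object@aSmall <= 0 || object@aLarge <= 0 || object@aColumn <= 0)
        return("areas must be > 0")
    if (object@aSmall > object@aLarge)
        return("aSmall must be <= aLarge")
    if (object@h0 <= 0 || object@rho <= 0 || object@g <= 0 ||
        object@mPiston <= 0 || object@travel <= 0)
        return("h0, rho, g, mPiston and travel must be > 0")
    if (object@damping < 0) return("damping must be >= 0")
    TRUE
})

#' @rdname PistonRig-class
#' @param aSmall,aLarge,aColumn,h0,rho,g,mPiston,damping,travel see slots.
#'   Defaults give a static hydraulic force of order 10 N under a 1.4 m
#'   water column.
#' @return A \code{PistonRig} object.
#' @export
PistonRig <- function(aSmall = 20e-4, aLarge = 27e-4, aColumn = 5e-4,
                      h0 = 1.4, rho = 1000, g = 9.81, mPiston = 0.5,
                      damping = 50, travel = 0.03) {
    new("PistonRig", aSmall = as.numeric(aSmall), aLarge = as.numeric(aLarge),
        aColumn = as.numeric(aColumn), h0 = as.numeric(h0),
        rho = as.numeric(rho), g = as.numeric(g),
        mPiston = as.numeric(mPiston), damping = as.numeric(damping),
        travel = as.numeric(travel))
}

#' State history of a piston simulation
#'
#' Time-ordered states of the rig: piston position \code{x} (0 = systolic
#' stop, \code{travel} = diastolic stop), velocity, water-column height,
#' hydraulic force and external pull, plus the cumulative net volume drawn
#' from the column.
#'
#' @slot times seconds, strictly increasing.
#' @slot x,v,h,force,fExt state vectors (m, m/s, m, N, N).
#' @slot displacedVolume net volume drawn from the column over the
#'   trajectory, m^3.
#' @slot rig the [PistonRig-class] that produced the trajectory.
#'
#' @name PistonTrajectory-class
#' @exportClass PistonTrajectory
setClass("PistonTrajectory",
    slots = c(times = "numeric", x = "numeric", v = "numeric", h = "numeric",
              force = "numeric", fExt = "numeric",
              displacedVolume = "numeric", rig = "PistonRig"))

setValidity("PistonTrajectory", function(object) {
    t <- object@times
    if (length(t) < 1L || any(diff(t) <= 0))
        return("times must be non-empty and strictly increasing")
    n <- length(t)
    if (length(object@x) != n || length(object@v) != n ||
        length(object@h) != n || length(object@force) != n ||
        length(object@fExt) != n)
        return("state vectors must all match the time grid length")
    if (any(object@x < -1e-12) ||
        any(object@x > object@rig@travel + 1e-12))
        return("piston position must stay within [0, travel]")
    if (any(object@h < 0)) return("column height must stay >= 0")
    TRUE
})
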