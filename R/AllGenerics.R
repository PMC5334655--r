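#' @include AllClasses.R
NULL

#' Evaluate an area curve at arbitrary cycle fractions
#'
#' Linear interpolation on the stored grid; exact at grid points.  Because the
#' curve is periodic, \code{areaAt(x, 1)} equals \code{areaAt(x, 0)}.
#'
#' @param x an [AreaCurve-class].
#' @param t cycle fraction(s) in \code{[0, 1]}.
#' @param ... unused.
#' @return Numeric vector of areas, cm^2.
#' @examples
#' crv <- buildCurve(ChamberLandmarks(14, 20, 16), defaultCyclePhases(),
#'                   nFrames = 30, chamber = "ASA")
#' areaAt(crv, c(0, 0.5, 1))
#' @export
setGeneric("areaAt", function(x, t, ...) standardGeneric("areaAt"))

#' Net hydraulic force over diastole for a subject or cohort
#'
#' @param x a [SubjectGeometry-class] or [AVAreaCohort-class].
#' @param pressures a [PressureModel-class].
#' @param ... unused.
#' @return A [ForceCurve-class] (subject) or a list of them (cohort).
#' @export
setGeneric("forceCurve",
           function(x, pressures = PressureModel(), ...)
               standardGeneric("forceCurve"))

#' Fraction of diastole with positive net hydraulic force
#'
#' @param x a [ForceCurve-class].
#' @param which \code{"endo"} or \code{"epi"}.
#' @param ... unused.
#' @return A fraction in \code{[0, 1]}.
#' @export
setGeneric("fractionDiastolePositive",
           function(x, which = c("endo", "epi"), ...)
               standardGeneric("fractionDiastolePositive"))

#' Extract one subject's geometry from a cohort
#'
#' @param x an [AVAreaCohort-class].
#' @param i subject index or subject id.
#' @param ... unused.
#' @return A [SubjectGeometry-class].
#' @export
setGeneric("subjectGeometry", function(x, i, ...)
    standardGeneric("subjectGeometry"))

#' Cycle phases stored in an object
#'
#' @param x an [AVAreaCohort-class] or [SubjectGeometry-class].
#' @return A [CyclePhases-class].
#' @export
setGeneric("cyclePhases", function(x) standardGeneric("cyclePhases"))

#' @rdname PistonTrajectory-class
#' @param x a [PistonTrajectory-class].
#' @export
setGeneric("trajectoryStates", function(x) standardGeneric("trajectoryStates"))

#' @rdname PistonTrajectory-class
#' @export
setGeneric("displacedVolume", function(x) standardGeneric("displacedVolume"))
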