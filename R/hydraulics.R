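#' @include geometry.R
NULL

## Exact definition of the conventional millimetre of mercury.
.PA_PER_MMHG <- 133.322368
.CM2_PER_M2 <- 1e4

#' Pressure unit conversion between mmHg and Pa
#'
#' Uses the exact conventional definition 1 mmHg = 133.322368 Pa.  The
#' conversion is sign-preserving and its round-trip is exact to floating
#' point.
#'
#' @param p pressure(s) in mmHg (for \code{mmHgToPa}) or Pa (for
#'   \code{paToMmHg}).
#' @return Converted pressure(s).
#' @examples
#' mmHgToPa(10)    # 1333.22... Pa, commonly rounded to 1333 Pa
#' paToMmHg(101325)
#' @export
mmHgToPa <- function(p) {
    if (any(!is.finite(p))) stop("pressure must be finite")
    p * .PA_PER_MMHG
}

#' @rdname mmHgToPa
#' @export
paToMmHg <- function(p) {
    if (any(!is.finite(p))) stop("pressure must be finite")
    p / .PA_PER_MMHG
}

#' Net hydraulic force on the AV plane (Pascal's principle)
#'
#' With the mitral valve open, the diastolic chamber pressure acts on both
#' sides of the atrioventricular plane; because the ventricular short-axis
#' area (VSA) differs from the atrial one (ASA) the resulting longitudinal
#' force is nonzero even at equal pressures:
#' \deqn{F = VSA \cdot P_{LV} - ASA \cdot P_{LA}}
#' Areas are entered in cm^2 and pressures in mmHg; the computation is done
#' in SI (m^2, Pa) and the result is in newtons.  Positive force points
#' apex-to-base, i.e. pushes the AV plane toward the atrium and aids filling.
#'
#' @param vsa ventricular short-axis area, cm^2 (> 0).
#' @param asa atrial short-axis area, cm^2 (> 0).
#' @param pLv ventricular pressure, mmHg (>= 0).
#' @param pLa atrial pressure, mmHg (>= 0, default \code{pLv}).
#' @return Force(s) in N.  Arguments recycle as usual.
#' @examples
#' netHydraulicForce(vsa = 23.7, asa = 16.0, pLv = 10)  # ~1.0 N
#' netHydraulicForce(vsa = 41.4, asa = 16.0, pLv = 10)  # ~3.4 N
#' @export
netHydraulicForce <- function(vsa, asa, pLv, pLa = pLv) {
    if (any(!is.finite(vsa)) || any(!is.finite(asa)) || any(vsa <= 0) ||
        any(asa <= 0))
        stop("areas must be finite and strictly positive (cm^2)")
    if (any(!is.finite(pLv)) || any(!is.finite(pLa)) || any(pLv < 0) ||
        any(pLa < 0))
        stop("pressures must be finite and >= 0 (mmHg)")
    mmHgToPa(pLv) * vsa / .CM2_PER_M2 - mmHgToPa(pLa) * asa / .CM2_PER_M2
}

.forceCurveFromGeometry <- function(subject, pressures) {
    validObject(pressures)
    tEs <- subject@phases@tEs
    grid <- subject@asa@times
    times <- c(tEs, grid[grid > tEs])
    if (abs(times[1L] - times[2L]) < 1e-12) times <- times[-1L]
    asa <- areaAt(subject@asa, times)
    endo <- areaAt(subject@vsaEndo, times)
    epi <- areaAt(subject@vsaEpi, times)
    new("ForceCurve",
        subjectId = subject@asa@subjectId,
        times = times,
        forceEndo = netHydraulicForce(endo, asa, pressures@pLv, pressures@pLa),
        forceEpi = netHydraulicForce(epi, asa, pressures@pLv, pressures@pLa))
}

#' @rdname forceCurve
setMethod("forceCurve", "SubjectGeometry", function(x, pressures = PressureModel(), ...) {
    .forceCurveFromGeometry(x, pressures)
})

#' @rdname forceCurve
setMethod("forceCurve", "AVAreaCohort", function(x, pressures = PressureModel(), ...) {
    lapply(seq_len(ncol(x)), function(i)
        .forceCurveFromGeometry(subjectGeometry(x, i), pressures))
})

## Lebesgue measure of {f > 0} for the piecewise-linear interpolant of
## (t, f); sign changes are located by linear interpolation within the
## bracketing interval, so the result is grid-resolution independent up to
## the interpolation error of the samples themselves.
.positiveMeasure <- function(t, f) {
    dt <- diff(t)
    f1 <- f[-length(f)]
    f2 <- f[-1L]
    contrib <- ifelse(f1 > 0 & f2 > 0, dt,
               ifelse(f1 <= 0 & f2 <= 0, 0,
               ifelse(f1 > 0, dt * f1 / (f1 - f2), dt * f2 / (f2 - f1))))
    sum(contrib)
}

#' @rdname fractionDiastolePositive
setMethod("fractionDiastolePositive", "ForceCurve",
          function(x, which = c("endo", "epi"), ...) {
    which <- match.arg(which)
    f <- if (which == "endo") x@forceEndo else x@forceEpi
    t <- x@times
    if (length(t) < 2L) stop("force curve is empty")
    .positiveMeasure(t, f) / (t[length(t)] - t[1L])
})
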