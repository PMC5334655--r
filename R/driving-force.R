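#' @include hydraulics.R
NULL

#' Total inertial load of early diastolic filling
#'
#' The inertial load is the total mass set in motion during early filling:
#' the LV myocardium plus the accelerated blood and great-vessel roots.
#'
#' @param lvMass left-ventricular mass, g.
#' @param extraMin,extraMax bounds on the extra (blood + vessel-root) mass, g.
#' @return Numeric length-2 vector \code{c(min, max)} in g.
#' @examples
#' inertialLoadRange(125, 75, 275)   # 200 400
#' @export
inertialLoadRange <- function(lvMass, extraMin, extraMax) {
    v <- c(lvMass, extraMin, extraMax)
    if (any(!is.finite(v)) || any(v < 0))
        stop("masses must be finite and >= 0")
    if (extraMin > extraMax) stop("extraMin must be <= extraMax")
    c(lvMass + extraMin, lvMass + extraMax)
}

#' Peak driving force from force-per-unit-mass and inertial load
#'
#' @param fPerMass force per unit mass, mN/g (about 25 mN/g in young healthy
#'   subjects).
#' @param load inertial load, g.
#' @return Force in N (vectorized).
#' @examples
#' peakDrivingForce(25, c(200, 400))   # 5 10
#' @export
peakDrivingForce <- function(fPerMass, load) {
    if (any(!is.finite(fPerMass)) || any(!is.finite(load)) ||
        any(fPerMass < 0) || any(load < 0))
        stop("fPerMass and load must be finite and >= 0")
    fPerMass * load / 1000
}

#' Hydraulic force as a fraction of the peak driving force
#'
#' Extreme ratios of the hydraulic-force range over the driving-force range:
#' \code{(fhMin/fdMax, fhMax/fdMin)}.
#'
#' @param fhMin,fhMax hydraulic-force range, N (> 0).
#' @param fdMin,fdMax driving-force range, N (> 0).
#' @return Numeric length-2 vector of fractions \code{c(min, max)}.
#' @examples
#' hydraulicFraction(1, 3, 5, 10)   # 0.1 0.6, i.e. 10--60%
#' @export
hydraulicFraction <- function(fhMin, fhMax, fdMin, fdMax) {
    v <- c(fhMin, fhMax, fdMin, fdMax)
    if (any(!is.finite(v)) || any(v <= 0))
        stop("all forces must be finite and > 0")
    if (fhMin > fhMax || fdMin > fdMax)
        stop("range minima must not exceed maxima")
    c(fhMin / fdMax, fhMax / fdMin)
}

#' Assemble a peak driving-force estimate
#'
#' @param fPerMass force per unit mass, mN/g.
#' @param lvMass LV mass, g.
#' @param extraMin,extraMax extra inertial mass bounds, g.
#' @return A [DrivingForceEstimate-class].
#' @examples
#' estimateDrivingForce()   # 200-400 g load, 5-10 N force
#' @export
estimateDrivingForce <- function(fPerMass = 25, lvMass = 125,
                                 extraMin = 75, extraMax = 275) {
    load <- inertialLoadRange(lvMass, extraMin, extraMax)
    force <- peakDrivingForce(fPerMass, load)
    new("DrivingForceEstimate", fPerMass = as.numeric(fPerMass),
        lvMass = as.numeric(lvMass),
        extraMin = as.numeric(extraMin), extraMax = as.numeric(extraMax),
        loadMin = load[1L], loadMax = load[2L],
        forceMin = force[1L], forceMax = force[2L])
}
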