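#' @include driving-force.R
NULL

#' Static net force on the piston
#'
#' Hydrostatic pressure at the piston axis acts equally per unit area on both
#' piston faces; the area difference yields a net force
#' \eqn{\rho g h (A_{large} - A_{small}) - f_{ext}} toward the small
#' ("atrial") chamber.
#'
#' @param rig a [PistonRig-class].
#' @param h current water-column height, m (default the rig's \code{h0}).
#' @param fExt external force pulling toward the large chamber, N.
#' @return Net force in N, positive toward the small chamber.
#' @examples
#' rig <- PistonRig(aSmall = 10e-4, aLarge = 20e-4)
#' staticNetForce(rig)   # ~13.7 N under a 1.4 m column
#' @export
staticNetForce <- function(rig, h = rig@h0, fExt = 0) {
    validObject(rig)
    if (any(!is.finite(h)) || any(h < 0)) stop("column height must be >= 0")
    if (any(!is.finite(fExt))) stop("external force must be finite")
    rig@rho * rig@g * h * (rig@aLarge - rig@aSmall) - fExt
}

## Column height is slaved to piston position by incompressibility: moving
## the piston by dx toward the small chamber draws (aLarge - aSmall) dx from
## the standpipe.  Using the algebraic constraint instead of integrating
## dh/dt keeps the volume ledger exact.
.heightAt <- function(rig, x, x0, h0) {
    h0 - (rig@aLarge - rig@aSmall) * (x - x0) / rig@aColumn
}

## Fixed-step classic RK4 on (x, v) with inelastic clamping at the stops.
.simulatePiston <- function(rig, x0, dt, tEnd, pull) {
    validObject(rig)
    if (!.scalarOk(dt) || dt <= 0) stop("dt must be > 0")
    if (!.scalarOk(tEnd) || tEnd <= 0) stop("tEnd must be > 0")
    if (!.scalarOk(x0) || x0 < 0 || x0 > rig@travel)
        stop("x0 must lie within [0, travel]")
    dA <- rig@aLarge - rig@aSmall
    nStep <- max(1L, as.integer(ceiling(tEnd / dt - 1e-9)))
    times <- x <- v <- h <- force <- fext <- numeric(nStep + 1L)

    accel <- function(xi, vi, fe) {
        hi <- .heightAt(rig, xi, x0, rig@h0)
        (rig@rho * rig@g * hi * dA - fe - rig@damping * vi) / rig@mPiston
    }

    xi <- x0; vi <- 0; ti <- 0
    fe0 <- pull(0)
    times[1L] <- 0; x[1L] <- xi; v[1L] <- vi
    h[1L] <- rig@h0; force[1L] <- rig@rho * rig@g * rig@h0 * dA; fext[1L] <- fe0

    for (k in seq_len(nStep)) {
        feA <- pull(ti); feB <- pull(ti + dt / 2); feC <- pull(ti + dt)
        if (!is.finite(feA) || !is.finite(feB) || !is.finite(feC))
            stop("numerical failure: non-finite external force")
        k1x <- vi;                 k1v <- accel(xi, vi, feA)
        k2x <- vi + dt / 2 * k1v;  k2v <- accel(xi + dt / 2 * k1x, k2x, feB)
        k3x <- vi + dt / 2 * k2v;  k3v <- accel(xi + dt / 2 * k2x, k3x, feB)
        k4x <- vi + dt * k3v;      k4v <- accel(xi + dt * k3x, k4x, feC)
        xi <- xi + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
        vi <- vi + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
        if (!is.finite(xi) || !is.finite(vi))
            stop("numerical failure: non-finite state during integration")
        ## inelastic stop contact: clamp position, zero inbound velocity
        if (xi >= rig@travel) {
            xi <- rig@travel
            if (vi > 0) vi <- 0
        } else if (xi <= 0) {
            xi <- 0
            if (vi < 0) vi <- 0
        }
        ti <- k * dt
        hi <- .heightAt(rig, xi, x0, rig@h0)
        if (hi < 0) stop("numerical failure: water column exhausted (h < 0)")
        times[k + 1L] <- ti; x[k + 1L] <- xi; v[k + 1L] <- vi; h[k + 1L] <- hi
        force[k + 1L] <- rig@rho * rig@g * hi * dA
        fext[k + 1L] <- feC
    }
    new("PistonTrajectory", times = times, x = x, v = v, h = h,
        force = force, fExt = fext,
        displacedVolume = dA * (xi - x0), rig = rig)
}

#' Simulate spontaneous piston return ("diastole")
#'
#' Releases the piston at position \code{x0} with zero velocity and no
#' external force, and integrates
#' \eqn{m \dot v = \rho g h (A_{large}-A_{small}) - c v} with the
#' water-column height coupled to the displaced volume.  With
#' \code{aLarge > aSmall} the piston moves spontaneously toward the small
#' chamber, mimicking the diastolic return of the AV plane, and comes to rest
#' at the stop (inelastic contact).
#'
#' @param rig a [PistonRig-class].
#' @param x0 initial position, m (0 = "systolic" stop).
#' @param dt fixed integrator step, s.
#' @param tEnd simulated time, s.
#' @return A [PistonTrajectory-class].
#' @examples
#' traj <- simulateRelease(PistonRig(), x0 = 0, dt = 1e-3, tEnd = 0.5)
#' tail(trajectoryStates(traj), 2)
#' @export
simulateRelease <- function(rig, x0 = 0, dt = 1e-4, tEnd = 1) {
    .simulatePiston(rig, x0, dt, tEnd, function(t) 0)
}

#' Simulate a pulled stroke ("systole") and what follows
#'
#' Same dynamics as [simulateRelease()] with a time-varying external force
#' \code{pullProfile(t)} (N, positive toward the large chamber).  A pull
#' exceeding the hydraulic term drives the piston toward the large chamber
#' (the "ventricular contraction" phase of the rig); once the profile returns
#' to zero the trajectory continues as a free release.
#'
#' @param rig a [PistonRig-class].
#' @param pullProfile function of time (s) returning the pull, N.
#' @param dt fixed integrator step, s.
#' @param tEnd simulated time, s.
#' @param x0 initial position, m (default: the "diastolic" stop).
#' @return A [PistonTrajectory-class].
#' @export
simulateStroke <- function(rig, pullProfile, dt = 1e-4, tEnd = 1,
                           x0 = rig@travel) {
    if (!is.function(pullProfile)) stop("pullProfile must be a function of time")
    .simulatePiston(rig, x0, dt, tEnd, pullProfile)
}

#' @rdname PistonTrajectory-class
#' @export
setMethod("trajectoryStates", "PistonTrajectory", function(x) {
    data.frame(t_s = x@times, x_m = x@x, v_m_s = x@v, h_m = x@h,
               force_N = x@force, f_ext_N = x@fExt)
})

#' @rdname PistonTrajectory-class
#' @export
setMethod("displacedVolume", "PistonTrajectory", function(x) x@displacedVolume)

.trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Energy audit of a piston trajectory
#'
#' Trapezoidal work/energy bookkeeping along the trajectory: work done by the
#' hydraulic force, work done against the external pull, viscous dissipation
#' and the kinetic-energy change.  For a free release the balance
#' \eqn{\Delta KE + E_{damp} \le W_{hyd}} holds, the gap being the kinetic
#' energy destroyed at the inelastic stop plus integration error.
#'
#' @param traj a [PistonTrajectory-class].
#' @return Named list with components \code{workHydraulic}, \code{workExternal}
#'   (work done by the pull on the piston, negative when opposing motion),
#'   \code{dissipated}, \code{kineticChange}, all in J.
#' @export
pistonEnergyAudit <- function(traj) {
    stopifnot(is(traj, "PistonTrajectory"))
    rig <- traj@rig
    list(workHydraulic = .trapz(traj@times, traj@force * traj@v),
         workExternal = .trapz(traj@times, -traj@fExt * traj@v),
         dissipated = .trapz(traj@times, rig@damping * traj@v^2),
         kineticChange = rig@mPiston / 2 *
             (traj@v[length(traj@v)]^2 - traj@v[1L]^2))
}
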