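#' @include pipeline.R
NULL

setMethod("show", "CyclePhases", function(object) {
    cat("CyclePhases (fractions of cycle)\n")
    cat(sprintf("  end systole %.4f | endo crossover %.4f | mid diastasis %.2f | atrial kick %.2f\n",
                object@tEs, object@tCrossEndo, object@tDd, object@tAk))
})

setMethod("show", "ChamberLandmarks", function(object) {
    cat(sprintf("ChamberLandmarks (cm^2): ED %.1f, ES %.1f, diastasis %.1f\n",
                object@aEd, object@aEs, object@aDd))
})

setMethod("show", "AreaCurve", function(object) {
    cat(sprintf("AreaCurve: %s, subject %s, %d frames, area %.1f-%.1f cm^2\n",
                object@chamber, object@subjectId, length(object@times),
                min(object@areas), max(object@areas)))
})

setMethod("show", "SubjectGeometry", function(object) {
    cat(sprintf("SubjectGeometry: subject %s, %d frames\n",
                object@asa@subjectId, length(object@asa@times)))
    show(object@phases)
})

setMethod("show", "AVAreaCohort", function(object) {
    cat(sprintf("AVAreaCohort: %d subjects x %d frames\n",
                ncol(object), nrow(object)))
    callNextMethod()
})

setMethod("show", "PressureModel", function(object) {
    cat(sprintf("PressureModel: LA %.1f mmHg, LV %.1f mmHg%s\n",
                object@pLa, object@pLv,
                if (object@equalPressure) " (equal-pressure mode)" else ""))
})

setMethod("show", "ForceCurve", function(object) {
    cat(sprintf("ForceCurve: subject %s, diastole t in [%.3f, %.3f], %d samples\n",
                object@subjectId, object@times[1L],
                object@times[length(object@times)], length(object@times)))
    cat(sprintf("  endo force %.2f to %.2f N; epi force %.2f to %.2f N\n",
                min(object@forceEndo), max(object@forceEndo),
                min(object@forceEpi), max(object@forceEpi)))
})

setMethod("show", "DrivingForceEstimate", function(object) {
    cat(sprintf("DrivingForceEstimate: %.0f mN/g x %.0f-%.0f g load -> %.1f-%.1f N\n",
                object@fPerMass, object@loadMin, object@loadMax,
                object@forceMin, object@forceMax))
})

setMethod("show", "PistonRig", function(object) {
    cat(sprintf("PistonRig: ends %.1f / %.1f cm^2, column %.0f cm x %.1f cm^2\n",
                1e4 * object@aSmall, 1e4 * object@aLarge,
                100 * object@h0, 1e4 * object@aColumn))
    cat(sprintf("  m %.2f kg, damping %.0f N s/m, travel %.0f mm, static force %.1f N\n",
                object@mPiston, object@damping, 1000 * object@travel,
                staticNetForce(object)))
})

setMethod("show", "PistonTrajectory", function(object) {
    n <- length(object@times)
    cat(sprintf("PistonTrajectory: %d states over %.3f s\n",
                n, object@times[n]))
    cat(sprintf("  x %.1f -> %.1f mm, final v %.3f m/s, column %.1f -> %.1f cm\n",
                1000 * object@x[1L], 1000 * object@x[n], object@v[n],
                100 * object@h[1L], 100 * object@h[n]))
})
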