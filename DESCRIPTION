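Package: AVHydraulics
Title: Hydraulic Forces Acting on the Atrioventricular Plane During
    Diastolic Filling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the hydraulic force that equal left-atrial and
    left-ventricular diastolic pressures exert on the atrioventricular
    (AV) plane as a consequence of the atrial short-axis area (ASA) being
    smaller than the ventricular short-axis area (VSA), following
    Pascal's principle.  Provides a seeded generator for synthetic
    cohorts of ASA/VSA area-time curves over the normalized cardiac
    cycle, net hydraulic force computation with strict SI unit handling,
    comparison against the estimated peak driving force of ventricular
    filling, exact small-sample Wilcoxon signed-rank statistics with
    mean +/- SEM summaries, and a dynamic simulation of a water-column
    pressurized hollow-piston rig that demonstrates spontaneous
    "diastolic" piston return driven by hydraulic force alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Cardiology, Physiology, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'hydraulics.R'
    'driving-force.R'
    'piston.R'
    'cohort-stats.R'
    'io.R'
    'pipeline.R'
    'show-methods.R'
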