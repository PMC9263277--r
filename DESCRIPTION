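Package: isofv
Title: Isokinetic Force-Velocity Profiling and Two-Point Method Screening
Version: 0.1.0
Authors@R:
    person("Matija", "Kres", email = "isofv@posteo.net", role = c("aut", "cre"))
Description: Tools for force-velocity (F-v) profiling of single-joint isokinetic
    strength tests. Converts dynamometer torque-time traces into per-velocity
    peak torques (zero-phase Butterworth filtering, isokinetic plateau
    detection, repetition peak extraction), maps peak torque to allometrically
    normalized force and linear velocity, and fits linear, polynomial and
    two-point F-v profiles (F0, v0, Sfv, Pmax). Includes the method-agreement
    statistics battery used to validate simplified two-point protocols against
    multi-point references (paired t, Cohen's d, two-way mixed intraclass
    correlations with confidence intervals, SEM, CV with chi-square confidence
    intervals, minimal detectable change, Bland-Altman limits of agreement),
    a screener over all two-velocity combinations of a test protocol, and a
    Hill-muscle synthetic cohort generator for end-to-end validation without
    access to raw dynamometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
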