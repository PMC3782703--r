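Package: fcloo
Title: Leave-One-Out Functional Connectivity Classification for Multisite Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-subject classification from resting-state
    functional connectivity in multisite cohorts. Implements per-connection
    dual-group general linear models with demographic covariates, site
    mean-offset harmonization, F-weighted connection scores aggregated over a
    lattice of regions of interest under strict leave-one-out discipline, and
    the surrounding pipeline: BOLD time-series cleaning (detrend, bandpass,
    nuisance regression, framewise-displacement/DVARS motion scrubbing),
    Fisher-z association matrices, connection strength-by-distance binning,
    exact binomial significance of classification accuracy, and a synthetic
    multisite cohort generator with planted group effects for calibration and
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
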