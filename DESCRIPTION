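Package: shiftdecode
Title: Spatial-Shift Cross-Classification Decoding of fMRI Feedback Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for measuring the spatial
    precision of contextual feedback signals in early visual cortex with
    multivoxel pattern analysis. Generates multi-subject, multi-run BOLD-like
    datasets whose condition patterns decay in similarity across parametric
    spatial shifts of the stimulus image, estimates single-trial response
    amplitudes with a general linear model, selects feedback (occluded,
    non-stimulated) and feedforward (stimulated) regions of interest from
    checkerboard mapping contrasts, decodes scene identity with a linear
    support vector machine under leave-one-run-out cross-validation --- within
    and across shifts, on single-trial and averaged-block patterns --- and
    summarises cohorts with a two-level bootstrap (percentile confidence
    intervals) and permutation difference tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
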