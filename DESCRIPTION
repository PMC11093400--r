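Package: gssfroi
Title: Group-Constrained Subject-Specific Functional ROI Analysis for fMRI Localizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject-specific functional-localizer analysis of fMRI
    data: first-level general linear models with a double-gamma hemodynamic
    response function, group-constrained subject-specific (GSS) parcellation of
    probabilistic overlap maps via watershed segmentation, top-fraction
    functional region-of-interest (fROI) definition with across-run
    cross-validation, percent-signal-change extraction, and network-level
    linear mixed-effects inference with crossed subject and ROI random effects.
    Includes a synthetic BOLD phantom generator (blocked and event-related
    designs, spatially jittered subject topographies, AR(1) noise and drift)
    so that every stage of the pipeline can be exercised and validated
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
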