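Package: cordvcm
Title: Along-Cord Tractometry with Varying Coefficient Models for Spinal Cord MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tract-specific along-cord analysis of spinal cord diffusion MRI.
    Extracts per-tract diffusion metric profiles (FA, MD, RD, AD) and cord
    cross-sectional-area profiles over cervical levels C2-C6 from scalar
    volumes, tract confidence maps and streamlines; fits a varying
    coefficient model of metric profiles on subject covariates by
    local-linear kernel weighted least squares; tests level-localized group
    effects with wild-bootstrap max-statistic family-wise correction,
    including a joint multimodal FA+CSA test and a longitudinal
    change-profile variant; and provides clinical scoring utilities
    (ALSFRS-R sub-scores, correlations, paired tests, onset-site subgroup
    summaries). Includes a synthetic cohort and voxel phantom generator for
    validation studies, plus a reproducible pipeline driver with TSV/NIfTI/TRK
    input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
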