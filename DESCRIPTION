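Package: lipidmrm
Title: Targeted Lipidomics MRM Library Construction, Validation and
    Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds class-specific multiple reaction monitoring (MRM)
    transition libraries for targeted triple-quadrupole lipidomics from an
    enumerated fatty-acyl chain space, computes monoisotopic precursor and
    product ion m/z values from elemental compositions, validates compound
    annotations with Kendrick mass defect (CH2 base) grid checks,
    performs internal-standard semi-quantification with the accompanying
    method-validation statistics (recovery, linearity, LOD/LOQ,
    repeatability), and analyses lipid trends against fruit ripeness
    (degrees Brix) with PCA and a resampling- and permutation-validated
    partial least squares regression. Includes a synthetic-data module
    that simulates maturation studies and spike designs with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
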