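Package: eyeirr
Title: Eye Irritation Hazard Classification from Reconstructed Cornea Viability Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for an in vitro eye irritation test on a
    reconstructed human cornea-like epithelium (RhCE) model. Converts
    dual-wavelength WST-8 plate-reader absorbances into blank-corrected
    optical densities and relative tissue viabilities, applies a
    multi-timepoint threshold framework (EC70 cut-off at post-incubation
    day 1, 50 percent recovery criterion at days 7 and 14) to assign
    liquid chemicals to UN GHS ocular-hazard categories (Category 1,
    Category 2, No Category), and computes the validation statistics
    (sensitivity, specificity, accuracy, per-category predictivity,
    balanced accuracy) used to judge a test method against OECD TG 492
    and TG 492B performance criteria. Includes a 31-chemical liquid
    reference panel and a synthetic plate-data generator so the whole
    pipeline is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
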