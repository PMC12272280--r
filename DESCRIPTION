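Package: waterbeq
Title: Effect-Based Water Quality Evaluation from In Vitro Bioassay Plate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for effect-based evaluation of water quality from
    high-throughput in vitro bioassay plate data. Normalizes 384-well
    reporter-gene, oxidative-stress and neurite-outgrowth readouts, fits
    concentration-response curves (linear below a 30 percent effect cutoff and
    four-parameter log-logistic), and derives benchmark concentrations (EC10,
    EC at induction ratio 1.5, IC10) with standard errors by error propagation
    and a confidence gate. Converts sample benchmarks into bioanalytical
    equivalent concentrations (BEQ) with uncertainty, computes cytotoxicity
    specificity ratios, applies effect-based trigger values (EBT), and performs
    concentration-addition iceberg modeling that compares measured mixture
    effects with effects predicted from quantified chemicals. Includes a
    synthetic-data generator with known ground truth emulating 11-point serial
    dilution designs, so every pipeline stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
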