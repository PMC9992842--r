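Package: gngtrace
Title: Direct Contribution of Circulating Substrates to Glucose from
    Stable-Isotope Tracer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of steady-state U-13C tracer infusion experiments in
    which circulating gluconeogenic substrates (lactate, glycerol, alanine)
    are traced into glucose. Provides natural-abundance correction of mass
    isotopomer distributions, atom-labeling and tracer-normalized labeling
    computations, estimation of non-negative direct contribution fractions
    by constrained least squares with Monte Carlo error propagation,
    enrichment summaries for isolated-mitochondria 13C-pyruvate
    incubations, and a forward simulator of tracer infusion experiments
    with known ground truth for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
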