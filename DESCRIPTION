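Package: alphasphere
Title: Multicellular Dosimetry and Tumor Control Modeling for Targeted
    Alpha Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates alpha-emitter irradiation of multicellular tumor
    spheroids for targeted alpha therapy dosimetry. Generates compacted
    spheroid cell populations, samples intracellular decay positions
    (membrane, cytoplasm, whole cell or nucleus) with uniform or lognormal
    intratumoral activity, transports alpha particles as straight
    continuous-slowing-down tracks against a packaged range table for liquid
    water, and records per-nucleus entry/exit energies. From the crossing
    records it computes nucleus specific energies and cross-fire fractions,
    cell survival under a pluggable lethal-function interface or a
    Charlton-style mean-free-path model, tumor control probability, relative
    biological effectiveness, and the activity or dose required for a target
    tumor control probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
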