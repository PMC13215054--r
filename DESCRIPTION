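Package: presynATP
Title: Presynaptic ATP Dynamics with Phosphagen Buffering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates adenine-nucleotide and phosphagen dynamics in presynaptic
    nerve terminals under action-potential firing protocols. ATP consumption is
    modelled as spike-and-decay costs per action potential plus a non-signalling
    base rate; ATP production responds to the cytosolic energy state
    [ATP]/([ADP][Pi]) with a rest-state calibration and a soft maximum-rate cap;
    adenylate-kinase and arginine-kinase equilibria are enforced at every step
    under pool conservation. Also implements the companion trace-processing
    procedures for ratiometric fluorescence imaging (background subtraction,
    delta-R/R, monoexponential bleach correction), median-absolute-deviation
    outlier screening, and quantal-content estimation with non-linear summation
    correction, together with synthetic-data generators so every component is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
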