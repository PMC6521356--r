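Package: her4switch
Title: HER4-JAK2-STAT5 Signaling Dynamics and Global Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic two-compartment mass-action model of the
    HER4-JAK2-STAT5 signaling pathway in mammary epithelial cells, including
    competitive HER4 heterodimerization with other ErbB receptors and a slower
    JAK2-independent activation of STAT5 through the cleaved HER4 s80 fragment.
    Simulates beta-casein gene expression under Neuregulin (NRG) dose series,
    computes interval-integrated expression, the early/late pathway switch
    ratio and the STAT5-to-mRNA transcription delay, propagates parameter
    uncertainty with Latin hypercube ensembles, and estimates first-order and
    total-effect Sobol sensitivity indices with Saltelli sample designs built
    on quasi-random Sobol sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    MASS,
    pracma,
    stats,
    utils,
    withr,
    xml2,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
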