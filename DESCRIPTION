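Package: fluxmodules
Title: Characterisation and Comparison of Metabolic Flux Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises the steady-state flux space of a genome-scale
    metabolic model under different constraint conditions and extracts the
    reaction modules that distinguish them. The workflow reads an SBML model,
    applies condition-specific bounds, removes blocked reactions by flux
    variability analysis, approximates the first two moments of the uniform
    flux distribution by expectation propagation (with a hit-and-run sampler
    as an independent route), decomposes the flux covariance by PCA with
    varimax rotation into high-loading reaction modules, compares conditions
    by bootstrapped independent component analysis with stability-based model
    selection and knee-point feature selection, and exports the resulting
    modules as annotated reaction and metabolite-reaction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
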