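Package: qresponse
Title: Symbolic Quasi-Energy Response Functions for Density-Matrix and
    Coupled-Cluster Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs time-averaged quasi-energy Lagrangians for atomic
    orbital density-matrix self-consistent-field and coupled-cluster
    electronic-structure models, differentiates them symbolically with
    respect to ordered collections of external perturbations, applies
    generalized 2n+1/2n+2 elimination rules to minimize the response
    parameters that remain to be solved, extracts right-hand sides of
    response equations, and evaluates the resulting expressions exactly
    for a two-level atom model using exact rational arithmetic.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
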