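Package: psdsim
Title: Stochastic Assembly and Differential Analysis of Postsynaptic
    Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based Gillespie simulation of multivalent binding among
    major postsynaptic density scaffold proteins; topology-aware canonical
    identification of the protein complexes formed; assembly of
    region-by-complex abundance matrices across brain regions; a
    PCA-derived per-complex relevance score identifying the most
    informative complexes; and paired wild-type versus hypomorphic-mutant
    comparison with Benjamini-Hochberg false-discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
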