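Package: rnacomposer
Title: Composite RNA Secondary-Structure Modelling from Multi-Modal Probing Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a composite secondary-structure model of a long
    transcript by integrating in-vitro nuclease probing (PARS S1/V1
    ratios), in-vivo chemical probing (DMS reactivity on A/C), and
    crosslink-ligation duplex groups (PARIS) under calibrated cutoffs,
    with windowed minimum-free-energy folding as fallback, pseudoknot
    calling, helix-level conservation and covariation scoring over
    homolog alignments, and functional-annotation overlay (miRNA sites,
    RNA modifications, mutations). Ships a synthetic-data generator that
    emulates the statistical structure of the probing modalities so the
    full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
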