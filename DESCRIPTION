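Package: orcnet
Title: Ollivier-Ricci Curvature and Robustness Analysis of Structural Brain
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the robustness of weighted structural brain
    networks (connectomes). Implements Ollivier-Ricci curvature of edges,
    nodes and whole graphs via exact Wasserstein-1 optimal transport,
    classical weighted graph measures (strength, betweenness centrality,
    Onnela clustering coefficient, density, efficiency, characteristic path
    length, diameter, small-worldness with degree-preserving surrogates),
    a cognitive-impairment index derived from neuropsychological test
    batteries, two-cohort nodewise and global comparisons with Holm-Sidak
    family-wise error control, measure-versus-impairment correlation, and a
    synthetic connectome cohort generator so that the complete pipeline can
    be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
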