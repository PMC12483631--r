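Package: chaoslearn
Title: Multiscale Topological Embedding of Data into Coupled Chaotic
    Oscillator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Embeds point clouds, multichannel signals, expression matrices
    and image feature vectors as nodes of a weighted network, derives a
    multiscale family of coupling matrices by kernel connectivity and a
    Laplacian filtration, computes persistent Laplacian spectra and
    persistent Betti numbers over Vietoris-Rips filtrations, evolves
    networks of diffusively coupled Lorenz or Rossler oscillators at each
    scale, and turns trajectory statistics into per-node features for
    quantitative prediction, including protein B-factor regression from
    C-alpha coordinates and cell-type classification with cross-validated
    balanced accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    class,
    MASS,
    Matrix,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
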