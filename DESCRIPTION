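Package: omtk
Title: Optical Map Construction, Assembly and Sequence-Discordance Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for whole-genome optical mapping in map space: in silico
    restriction digestion of sequence assemblies, simulation of single-molecule
    restriction maps (Rmaps) with realistic error channels, dynamic-programming
    alignment of ordered restriction maps with size-dependent sizing error,
    reference-seeded iterative consensus assembly, Germinate-and-Grow de novo
    assembly over a de Bruijn graph of geometrically quantized fragment k-mers,
    chromosome-wide map stitching, and classification of sequence-versus-map
    discordances (extra/missing cuts, extraneous/missing sequence, complex
    events, inversions and translocations), with planted-variant truth ledgers
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
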