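Package: svfem
Title: Finite-Element Biomechanics of the Cemented Sandwich Vertebra
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric finite-element pipeline for studying how the
    distribution of vertebroplasty bone cement in the vertebrae above and
    below an untreated "sandwich" vertebra changes the load on that
    vertebra and its discs.  Builds a synthetic T11-L1 segment (vertebral
    bodies with cortical shell and endplates, discs with annulus and
    nucleus, posterior elements, facet cartilage and seven tension-only
    ligament groups), meshes it with structured tetrahedra, solves the
    linear-elastic problem under six physiological load cases, and
    summarises von Mises stress, displacement and segmental range of
    motion across four cement-placement configurations.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
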