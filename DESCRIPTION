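Package: distspectra
Title: Distance-Spectral Descriptors of Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes distance-related spectral descriptors of molecular graphs:
    eleven chemical matrices (distance, distance Laplacian, distance signless
    Laplacian, Harary, Szeged, Padmakar-Ivan, degree-distance, Schultz, Gutman,
    second atom-bond connectivity and second geometric-arithmetic) together with
    their spectral radius, graph energy and Estrada invariants. Includes
    deterministic generators for polyhex carbon nanotube lattices, one-hexagonal
    nanocones and a catalogue of lower benzenoid hydrocarbons, plus the QSPR
    regression and descriptor-ranking protocol used to screen descriptors against
    thermodynamic properties such as heat capacity and entropy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
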