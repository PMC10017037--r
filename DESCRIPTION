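Package: cdvsim
Title: Coarse-Grained Simulation and Quantification of ESCRT-III-Driven
    Archaeal Cell Division
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and quantify membrane constriction by composite
    ESCRT-III polymers during Sulfolobus cell division. Provides a
    coarse-grained Langevin simulator of three mechanically distinct helical
    filaments (CdvB, CdvB1, CdvB2) adhering to a particle-based deformable
    membrane tube, with Vps4-style scheduled filament disassembly; trajectory
    reduction to axial filament-density profiles, separation scores and
    constriction traces; a synthetic fluorescence-microscopy generator
    (STED-like rings and bands, constriction time-lapses, cell images with
    ring and cytoplasmic pools) with embedded ground truth; and the matching
    quantification procedures (averaged line profiles, FWHM, face-on ring
    diameters and channel offsets, cytoplasmic signal fractions, constriction
    rates, cumulative abscission curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
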