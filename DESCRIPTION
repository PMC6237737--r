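Package: hgduplex
Title: Hoogsteen Base-Pair Energetics and Geometry in DNA and RNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting why Hoogsteen base pairs are disfavored in
    A-form RNA relative to B-form DNA. Implements two-state UV melting
    thermodynamics (duplex and hairpin models, least-squares curve fitting,
    free-energy ledgers with error propagation), nucleic-acid structural
    geometry (backbone and glycosidic torsions, sugar pseudorotation,
    base-pair geometry and Watson-Crick/Hoogsteen classification), a
    crystal-structure survey for purine-purine mismatches, an idealized
    A-/B-form helix builder with syn-flip and Hoogsteen placement editing,
    base-stacking overlap areas by polygon clipping, trajectory Hoogsteen
    occupancy and population free energies, and nearest-neighbor duplex
    thermodynamics with internal mismatches for DNA and RNA. A synthetic-data
    module generates melting curves and two-state trajectory descriptor
    series so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
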