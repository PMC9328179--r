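Package: peroscan
Title: Rule-Based Annotation of Peroxisomal Targeting Signals in Plant Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies C-terminal PTS1 tripeptides into canonical,
    non-canonical and no-obvious sub-categories using per-position residue
    abundance classes, scans protein N-termini (and optionally whole
    sequences) for degenerate PTS2 nonapeptides, locates internal
    catalase-type PTS1 motifs, computes positional residue propensity
    tables over nonapeptide sets, and assembles two-species comparative
    catalogues of putative peroxisomal matrix proteins.  Includes a
    synthetic proteome generator with ground-truth labels for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
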