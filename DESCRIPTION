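Package: shapeseqr
Title: Targeted In-Cell SHAPE-Seq Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted in-cell SHAPE-Seq chemical
    probing experiments. Converts paired-end probing reads into per-target
    reverse-transcriptase stop counts, estimates per-nucleotide modification
    probabilities (theta) with a drop-off-corrected maximum-likelihood
    model, normalizes them to rho reactivities, generates pseudo-free-energy
    constraints for minimum-free-energy RNA secondary structure prediction,
    couples reactivity changes to fluorescence-based gene-expression
    measurements (six-nucleotide Shine-Dalgarno window scan, window and
    expression fold changes), detects double-stranded RNase cleavage spikes
    in raw fragment distributions, and provides a generative read simulator
    for end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA (RNAfold executable on PATH) for the
    folding module.
Config/testthat/edition: 3
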