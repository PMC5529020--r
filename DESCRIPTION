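Package: epimap
Title: Linear B-Cell Epitope Mapping from High-Density Peptide Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying linear B-cell epitope elements
    in protein families (e.g. snake-venom toxins) from high-density overlapping
    peptide microarrays probed in two successive incubations. Provides peptide
    library design (15-mer tiling with single-residue displacement, replicate
    randomised layout, corner controls), two-recording signal correction using
    a re-incubation factor estimated from control peptides, running-median
    score profiles, bootstrap-calibrated one-sided Z-tests with
    Benjamini-Hochberg false-discovery-rate control, alignment-anchored
    epitope-segment and core-motif extraction, Shannon sequence-logo matrices,
    rank-based residue-association Z-scores, and projection of per-residue
    recognition scores onto protein structures. A synthetic-array module
    generates toxin sets, planted epitope motifs and two-channel intensity
    tables with the noise structure the analysis assumes, so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
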