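Package: mimicscreen
Title: In-Silico Screening for Microbial Mimics of a Self-Epitope at the
    MHC II-TCR Interface
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a molecular-mimicry screen for microbiome-derived
    peptides resembling an autoantigen at the residues contacted by MHC
    class II and the T-cell receptor. Compiles degenerate fixed-spacing
    motifs from an annotated epitope footprint, scans protein collections
    (optionally prefiltered by Smith-Waterman alignment with
    Karlin-Altschul e-values), truncates ligand windows, enumerates 9-mer
    binding cores within 11-mer windows, classifies MHC II binders from
    structure-prediction confidence scores (pLDDT and inter-chain PAE),
    selects best TCR-docking models, and profiles candidates by taxonomy
    and position-specific residue frequency. Includes a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
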