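Package: phagescan
Title: Phage-Display Biopanning Analysis: Insert Decoding, Tripeptide
    Motif Statistics, and Panning Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo phage-display peptide screens
    built on disulfide-constrained heptapeptide (C7C) libraries encoded
    with NNK degenerate codons. Extracts the 21-nt random insert from raw
    amplicon reads on either strand, enforces the NNK third-position G/T
    codon rule, translates inserts with amber (TAG) suppression,
    collapses redundant heptapeptides, counts bidirectional tripeptide
    abundance, assesses significance with a residue-shuffling permutation
    test under Bonferroni correction, and extends selected tripeptides
    into 4-6 residue consensus motifs by anchored alignment. Also
    provides plaque-titer arithmetic, round-wise recovery and enrichment
    profiles with saturation detection, ELISA fold-ratio classification
    of positive clones, and a fully seeded synthetic-data generator so
    every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
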