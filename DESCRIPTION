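Package: idrmotifs
Title: Mutational-Tolerance Landscapes and Conserved Motifs in Disordered Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing residue-level mutational tolerance of intrinsically
    disordered protein regions from protein-language-model log-likelihood-ratio (LLR)
    matrices. Computes a per-residue entropy score of the softmax over the 20 mutant
    LLRs, classifies residues by structural order (AlphaFold pLDDT) and mutational
    constraint, scores evolutionary conservation from reference-anchored multiple
    sequence alignments with a percent-identity filter, identifies conserved sequence
    motifs by a bidirectional greedy scan with intersection and proximity merging,
    classifies disordered regions against experimentally annotated phase-separation
    segments, and provides nonparametric group comparisons, per-amino-acid LLR
    profiles and clustering. Includes a seed-reproducible synthetic-data generator
    with planted ground truth and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
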