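Package: fgseq
Title: Sequence-Feature Analysis of FG Nucleoporins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the disordered regions of FG nucleoporins,
    the phenylalanine-glycine repeat proteins that form the permeability
    barrier of the nuclear pore complex. Computes per-protein charge and
    hydrophobicity composition (mean absolute net charge, charged-residue
    number density, normalized Kyte-Doolittle hydrophobicity, amino-acid
    abundance), extracts inter-motif FG linkers and their polar/charged
    composition, detects like-charge regions (maximal same-sign runs of
    charged residues), clusters FG motifs, charged and polar residues along
    the sequence with a one-dimensional density-based (DBSCAN-semantics)
    method tuned by Dunn's validity index, quantifies overlap between
    cluster types, and localizes clusters in three zones along the sequence.
    Includes a synthetic-sequence generator with planted, known ground truth
    so every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
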