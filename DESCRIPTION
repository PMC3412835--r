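Package: mitoarch
Title: Architecture, Strand Asymmetry and Rearrangement Analysis of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular mitochondrial
    genomes: feature-table, GenBank and FASTA input/output with 1-based inclusive
    circular coordinates; intergenic spacer and overlap accounting; nucleotide
    composition, codon-position composition and AT/GC strand-asymmetry (skew)
    statistics with sign-based skew classification; detection of tandem repeat
    units (unit length, full copies, partial terminal copy); combinatorial
    scanning of non-coding sequence for tRNA-like cloverleaf structures,
    stem-loops with conserved flanking motifs, poly-T stretches and open reading
    frames; classification of gene-order rearrangements (translocation, local
    inversion, shuffling with remote inversion) against the ancestral insect
    arrangement, including duplication/random-loss scenario modelling; and a
    seeded synthetic-genome generator with planted repeats, motifs and
    rearrangement events so every analysis stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
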