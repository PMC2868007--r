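Package: ddsm
Title: Substitution-Matrix-Aware Motif Encoding of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns labeled protein sequence sets (FASTA) into
    classifier-ready binary feature tables. Implements the Discriminative
    Descriptors with Substitution Matrix (DDSM) encoding: repeats are mined
    per family, filtered for discrimination and minimality, then clustered
    by substitution probability under an amino-acid substitution matrix
    (BLOSUM/PAM) so that mutually substitutable motifs collapse to a single
    main-motif feature, and presence marking accepts substitutes. Also
    provides the classic baseline encoders (N-grams, amino acid composition,
    active motifs, discriminative descriptors), ARFF/CSV writers, a
    synthetic fixture generator with implanted motifs, and a leave-one-out
    nearest-neighbour evaluation harness.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
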