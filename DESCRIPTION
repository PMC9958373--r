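Package: clonescreen
Title: Single-Cell B Cell Receptor Clonotyping, Repertoire Statistics, and
    Antigen-Specificity Screening
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for paired heavy/light-chain single-cell
    B cell receptor (BCR) repertoire analysis. Reads 10x Genomics
    filtered-contig annotation tables and AIRR Rearrangement files, enforces
    one-heavy-one-light cell quality control, groups cells into clonal
    families by identical CDRH3+CDRL3 amino-acid sequences, and computes
    clonal expansion profiles, isotype majorities, nucleotide/amino-acid
    variant counts, somatic hypermutation loads, inter-repertoire overlap
    (Jaccard), V-J pairing matrices, CDR3 position-frequency matrices, and
    edit-distance clone similarity networks. Implements rule-based selection
    of clones for recombinant antibody expression, ELISA binder
    classification with cohort summaries, and a minimal single-cell
    transcriptome stage (mitochondrial QC, Ig-gene removal, log
    normalization, variable-gene selection, PCA, graph clustering, Wilcoxon
    differential expression). A seeded synthetic-repertoire generator
    emulating cellranger-style outputs makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
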