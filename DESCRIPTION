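Package: sparsemotif
Title: Motif Discovery from Hierarchical Convolutional Sparse
    Representations of DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers primary, gapped, long and overlapping DNA motifs from
    unaligned sequence sets (e.g. ChIP-seq peaks) by learning a two-level
    convolutional sparse representation: position-frequency-matrix filters
    reconstruct one-hot DNA, their sparse codes form a per-sequence "code
    image", and a second bank of non-negative filters sparsely reconstructs
    that image. Spatial configurations of the image-level code components are
    enumerated into a hash table whose buckets define multiple sequence
    alignments, yielding position weight matrices that are merged by average
    log-likelihood ratio similarity and scored for enrichment against
    dinucleotide-preserving shuffled controls with Fisher's exact test.
    Includes an alternating ADMM/ISTA/mirror-descent solver, a deep-unfolded
    trainable variant of the same iterations, and a synthetic planted-motif
    data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
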