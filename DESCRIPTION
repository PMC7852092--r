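Package: attnbind
Title: Dual-Attention Neural Networks for Cross-Cell-Type Transcription
    Factor Binding Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts transcription factor binding at 200-bp genomic bins
    across cell types from DNA sequence, sequence uniqueness and chromatin
    accessibility. Implements the full pipeline: sliding-window genome
    binning with bound/unbound/ambiguous labeling from conservative and
    relaxed ChIP-Seq peak sets, per-strand sequential feature encoding,
    a Siamese convolutional Bi-LSTM network with single (position-wise)
    and pairwise (scaled dot-product) attention modules trained with
    iterative negative resampling, the four challenge evaluation metrics
    with the rank-based unified score, attention-based interpretation with
    motif-window extraction and PWM scanning, and a seeded synthetic-data
    generator that plants motifs and accessibility peaks so every stage is
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
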