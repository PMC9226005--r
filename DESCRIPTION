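Package: isomiRTarget
Title: miRNA and isomiR Target Detection from Chimeric Reads with a
    Convolutional-Recurrent Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts miRNA- and isomiR-mRNA interaction pairs from
    chimeric sequencing reads (CLASH/CLEAR-CLIP style experiments),
    classifies isomiR sequence variants into the eight canonical types,
    builds labelled training pairs with energy-screened negative target
    sites, trains a two-branch convolutional plus bidirectional-LSTM
    classifier of small RNA-target interactions, and interprets the
    trained model through convolutional-kernel motif analysis and
    sliding N-mask input perturbation.  Includes a synthetic-data
    generator (references, isomiRs, planted target sites, chimeric
    FASTQ reads and surrogate alignment hits) so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
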