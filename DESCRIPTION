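Package: nrekg
Title: Knowledge-Augmented Cross-Sentence N-Ary Relation Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extraction of drug-gene-mutation interaction types from
    multi-sentence biomedical text, augmented with knowledge-graph side
    information. Implements translation-model knowledge-graph embeddings
    (TransE, TransH, TransR, TransD) trained under the margin ranking loss
    with filtered negative sampling, a token encoder combining word and
    three-entity position embeddings with a bidirectional LSTM, multihead
    scaled dot-product self-attention, and a softmax classifier over the
    concatenation of the sentence representation and entity relation
    vectors. Ships corpus and knowledge-graph simulators with planted
    ground truth, cross-validation, and evaluation reports (accuracy,
    macro-F1, confusion matrices, sentence-length buckets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
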