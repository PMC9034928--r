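Package: drugner
Title: Multitask Drug Named-Entity Recognition and Normalization with a
    BiLSTM-CRF Sequence Labeler
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint drug named-entity recognition (DNER) and normalization
    (DNEN) by multitask sequence labeling. Token representations combine
    pretrained word vectors, a character-level convolutional network and
    contextual vectors from a small bidirectional language model mixed
    ELMo-style; a shared bidirectional LSTM feeds two task heads (a
    linear-chain CRF for BIO entity tagging and a per-token classifier for
    normalization IDs) that exchange explicit label feedback through trainable
    mapping matrices. Includes readers and writers for DDI-challenge-style XML
    and CoNLL-style BIO files, a synthetic-corpus generator with known ground
    truth, span-level evaluation under strict and type matching, and a
    deterministic asynchronous multitask training loop with SGD-family
    optimizers, learning-rate decay and gradient clipping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
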