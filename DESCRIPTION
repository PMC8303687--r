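Package: flavorlex
Title: Flavor Descriptor Extraction from Free-Text Reviews with a
    Dual-Branch LSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining sensory lexicons from free-text product
    reviews (whisky tasting notes and similar corpora). Implements the
    full pipeline: tokenisation and part-of-speech filtering of review
    text, frequency-ranked annotation queues with two-of-three annotator
    consensus, word-embedding lookup with a zero-vector PAD convention,
    context-window sequence construction, a dual-branch unidirectional
    LSTM token classifier trained with Adam (implemented natively over
    BLAS), a noun/adjective part-of-speech baseline, evaluation metrics,
    2-D embedding projections, per-review descriptor lexicon extraction,
    and a synthetic corpus/embedding generator for end-to-end testing
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
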