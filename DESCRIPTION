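Package: bilex
Title: Bilingual Term Lexicon Induction from Comparable Clinical Corpora
Version: 0.1.0
Authors@R: person("bilex", "maintainers", email = "bilex@example.org", role = c("aut", "cre"))
Description: Induces bilingual term lexicons from comparable (non-parallel)
    monolingual corpora with pre-annotated term spans. Implements a
    context-similarity baseline over seed-pair indexed context vectors, a
    graph-based label propagation method with clamped seed labels for
    single-word terms, a compositional alignment procedure for multi-word
    terms built on propagated labels, Top-N accuracy evaluation against a
    gold lexicon, and a synthetic comparable-corpus generator with planted
    translation pairs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
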