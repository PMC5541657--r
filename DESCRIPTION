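Package: gibarra
Title: Desk-Scale FM-Index Short-Read Alignment with Genetic Improvement
    of the Search Kernel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact Burrows-Wheeler/FM-index short-read alignment stack:
    reference indexing, exact backward search with a fast non-divergent
    pre-pass, a k-difference backtracking fallback for noisy reads,
    paired-end combination into SAM, and a read simulator with ground
    truth for accuracy scoring.  On top of the aligner sits a
    grammar-based genetic-improvement harness that evolves the search
    kernel's parameter and code-variant sites under an
    "equivalent answers, then faster" fitness with held-out validation,
    using a deterministic instrumented work-unit cost in place of
    wall-clock time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    Rsamtools
Config/testthat/edition: 3
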