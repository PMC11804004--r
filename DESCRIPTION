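Package: clinner
Title: Zero-Shot Clinical Named Entity Recognition Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for zero-shot clinical named entity
    recognition with generative language models. Builds a unified
    multiclass silver-standard corpus from per-category standoff
    annotation releases (diseases, symptoms, medical procedures) with
    longest-span overlap resolution and IOB conversion; renders three
    prompt templates of increasing structural strictness; parses raw
    model generations fault-tolerantly in keyed-list and JSON dialects;
    aligns recovered entities back onto source documents under two
    tagging strategies; and reports entity- and token-level precision,
    recall, F1 and the valid-output ratio. A seeded synthetic corpus
    generator and a parameterised generation simulator make every
    pipeline stage testable without model inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
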