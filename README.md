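# clinner — zero-shot clinical NER evaluation

`clinner` is an R package for evaluating generative language models on
zero-shot clinical named entity recognition. It is aimed at
biomedical-NLP practitioners who prompt an LLM to extract mentions of
**diseases, symptoms, and medical procedures** from clinical case
reports and then need a reproducible, auditable way to score the
free-text generations against token-level silver-standard annotations.

The pipeline covers:

1. **Corpus construction** — merging per-category standoff annotation
   releases (the DisTEMIST / SympTEMIST / MedProcNER TSV layout:
   `filename, label, start_span, end_span, text`) into one multiclass
   corpus, resolving cross-category span overlaps by keeping the
   longest span of each overlap cluster, assigning a train/test split
   from an explicit id list, and emitting IOB labels
   (`B-DISEASE`, `I-SYMPTOM`, ..., `O`) over an offset-preserving
   tokenization.
2. **Prompting** — three prompt templates of increasing structural
   strictness (free-form, keyed list, JSON annotations), rendered by
   substituting the clinical note for a placeholder sentinel.
3. **Generation I/O** — a backend contract (`llm_register_backend()`)
   with record/replay JSONL storage, so evaluation runs are
   reproducible without model weights; a parameterised simulator stands
   in for GPU inference.
4. **Fault-tolerant parsing** — recovery of per-category entity lists
   from the malformed dialects models actually emit: unquoted JSON
   keys and values, typographic quotes, unterminated brackets,
   bracketless bulleted lists, trailing commas, prose around the
   structure.
5. **Two alignment strategies** — strategy 1 asks, category-blind,
   whether each silver term occurs (completely or partially) in the
   generation and tags *all* its document occurrences with bare `B`/`I`
   tags; strategy 2 takes the parsed per-category entities, matches
   them back into the document, and tags all occurrences with
   categorical tags. Hallucinated entities (absent from the document)
   can never tag anything.
6. **Metrics** — entity-level (strict span + label) and token-level
   precision / recall / F1 per category with pooled micro averages
   (P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R)), plus the
   valid-output ratio: the fraction of documents whose generation
   yielded at least one correctly parsed entity.

A partial match is defined as a proper contiguous subsequence of the
term's tokens of length ≥ ⌈n/2⌉ containing at least one non-stopword
token; matching is case-insensitive and whitespace/punctuation
normalized, with no stemming or fuzzy matching.

## Worked example

```r
library(clinner)

# a keyed-list generation as a model actually produced it
raw <- readr::read_file(system.file("extdata", "example_output_keyed.txt",
                                    package = "clinner"))
p <- parse_keyed_list(raw)
lengths(p$entities)
#>   DISEASE   SYMPTOM PROCEDURE
#>         1         9        11
p$entities$DISEASE
#> [1] "renal hydatid disease"

# a truncated pseudo-JSON generation: structure recovered, but neither
# annotation object carries a canonical category, so nothing is scored
raw3 <- readr::read_file(system.file("extdata", "example_output_json.txt",
                                     package = "clinner"))
p3 <- parse_json_annotations(raw3)
c(p3$n_objects, sum(lengths(p3$entities)), parsed_ok(p3))
#> [1] 2 0 0

# end to end on synthetic data with known ground truth
gen <- generate_corpus(synthetic_spec(n_docs = 50, seed = 11))
outs <- simulate_outputs(gen$corpus,
                         simulator_params(recall_true = 0.4, seed = 7),
                         variations = 2L)
rep <- evaluate_run(gen$corpus, outs, modes = "ENTITY")
rep$strategy2[rep$strategy2$category == "micro avg",
              c("precision", "recall", "f1")]
#> # A tibble: 1 × 3
#>   precision recall    f1
#> 1         1  0.391 0.563
```

The simulated model emits each gold mention with probability 0.4 and
nothing else; the pipeline recovers precision 1 (hallucination-free by
construction) and recall ≈ 0.4, which is exactly the closed-form
prediction of `expected_metrics()`.

The stage commands `cmd_simulate()`, `cmd_merge()` and
`cmd_evaluate()` run the same pipeline from a YAML config and fixed
artifact layout (standoff TSVs, documents directory, outputs JSONL,
CoNLL gold files, report CSVs); `inst/scripts/clinner-cli.R` is a thin
shell wrapper around them.

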