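---
title: "Evaluating zero-shot clinical NER: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating zero-shot clinical NER: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinner)
```

## The evaluation problem

A generative model prompted with task instructions only — no training
examples — returns free text when asked to extract mentions of
diseases, symptoms and medical procedures from a clinical case. Scoring
that text against token-level silver-standard annotation requires three
mechanisms this package provides: a *corpus* whose per-category
annotations have been merged into one non-overlapping multiclass label
set; a *parser* that recovers entity lists from whatever dialect of the
requested structure the model produced; and an *aligner* that converts
recovered strings into IOB label sequences over the original document,
where standard precision/recall/F1 machinery applies.

The unit of comparison is always a label sequence over the same
tokenization of the same document. The package scores at two levels:
entity level (strict: a predicted mention counts only if its character
span and label both match a gold mention exactly) and token level
(positional comparison of non-`O` labels). Both are reported, clearly
labeled, because published scores in this area frequently leave the
level unstated; entity level is the default and the stricter of the
two.

## Corpus construction

Standoff annotations arrive as per-category TSV releases with 0-based
half-open character offsets. Merging the categories produces overlapping
spans (e.g. a disease span contained in a longer procedure span);
overlap clusters are the connected components of the pairwise
span-overlap relation — so a chain of overlaps forms one cluster — and
from each cluster exactly one mention survives: the longest. Ties are
broken by smaller start offset, then by the fixed category priority
DISEASE < SYMPTOM < PROCEDURE. Only "keep the longest" is a modeling
commitment; the tie-breaks exist to make output deterministic, and are
exercised directly by a brute-force cluster-then-argmax oracle in the
test suite. Overlap removal runs globally per document, not per source
corpus: once categories are merged there is no principled reason to
treat a within-source overlap differently from a cross-source one.

Tokenization is offset-preserving whitespace splitting with leading and
trailing punctuation peeled into their own tokens. This keeps silver
mention boundaries token-aligned in the common case ("(fever)." yields
a `fever` token exactly covering the mention). When a silver offset
still cuts through a token, the token joins the mention iff its span
midpoint lies inside the mention span — an arbitrary but deterministic
rule, logged with a warning. Mentions whose surface string disagrees
with the text slice are kept with a warning, trusting offsets:
machine-translated silver standards are known to carry such noise, and
silently dropping rows would bias mention counts.

The train/test split is supplied as an explicit id list rather than
recomputed, because the source corpora define their 90-document test
subset through an external corpus whose translations diverge from the
text the other releases share. Documents "common" to all releases are
those whose text every release ships — a common document may carry no
annotation of some category, which is normal (a quarter of the source
corpus has no disease mention).

CoNLL output is emitted one block per document. The releases carry no
usable sentence segmentation, and none of the scoring here depends on
sentence boundaries.

## Prompt templates

The three templates request, in order: no output format; a keyed
Python-dictionary-like list; a JSON `annotations` array. They are
stored with a sentinel placeholder (`{{CLINICAL_TEXT}}`) rather than a
human-readable legend so that no substring of a real clinical note can
collide with the placeholder. Rendering is pure string substitution and
is tested byte-for-byte. The templates are also exportable as YAML for
users who want to vary them; everything downstream is
template-agnostic.

## Fault-tolerant parsing

The parsers implement the observation that models rarely emit the
requested structure exactly, and that discarding near-miss structures
would conflate formatting ability with extraction ability (the
valid-output ratio measures formatting ability separately).

The keyed-list reader locates category keywords followed by a colon —
with or without braces, quotes, bullets or asterisks — and reads either
a bracketed list (tolerating a missing closing bracket) or, with a
diagnostic, a bracketless line-delimited list. Items split on
semicolons, commas and newlines outside any nested bracket or
parenthesis, are trimmed of bullets and trailing punctuation, and are
deduplicated case-insensitively keeping first occurrence (models that
restate "each symptom once" make list semantics the right reading).
When the generation restates the structure, the first occurrence of
each category key wins — models often repeat themselves, and taking the
first is deterministic.

The JSON reader finds the first brace region carrying an `annotations`
key and reads it with a tolerant recursive-descent reader: unquoted
keys and barewords become strings, typographic quotes pair with their
ASCII equivalents, trailing commas are skipped, and end of input closes
every open structure (truncated generations are the norm, not the
exception). Annotation objects missing an `entity`, or carrying a
category outside the canonical three (e.g. `"not applicable"`), are
dropped with a diagnostic rather than reassigned — guessing a category
would inject evaluator bias into category-level scores. On strictly
valid input both readers coincide with strict-grammar parsers, which is
a tested invariant, not an aspiration; and neither reader can raise on
arbitrary input (fuzz-tested).

`PARSED` status — and hence the valid-output ratio — requires at least
one canonical entity recovered. An intact but empty structure is
`EMPTY`; no recognizable structure is `UNPARSEABLE`. Both count against
the ratio.

## Matching and alignment

Matching between entity strings and text is deliberately narrow:
casefolding, whitespace collapsing and per-token edge-punctuation
stripping, with an offset map back to raw character positions — no
stemming, no edit distance, no synonym expansion. A COMPLETE match is
the normalized term at token boundaries. A PARTIAL match is a proper
contiguous subsequence of the term's tokens, of length at least
⌈n/2⌉, containing at least one non-stopword token, also at token
boundaries; the longest, then leftmost, qualifying window is chosen.
The ⌈n/2⌉ floor keeps the rule symmetric in spirit ("most of the
term"), and the stopword condition stops `"pain in the flank"` from
matching a text that merely contains `"in the"`. The stopword list is
a short fixed English list shipped with the package
(`ner_stopwords()`); laterality words like *left*/*right* are
deliberately not stopwords because they are clinically meaningful.
For a PARTIAL match, what gets tagged in the document are occurrences
of the *matched subsequence*, never the full term — tagging tokens the
model did not actually evidence would fabricate credit.

Strategy 1 iterates over distinct silver surface forms (instances of
the same string are indistinguishable to string matching), matches each
against the generation, and tags all document occurrences of matched
strings with bare `B`/`I` tags. Strategy 2 iterates over parsed
entities per category, matches each against the *document*, and tags
all occurrences categorically. In both, an entity absent from the
document tags nothing — this is the mechanism by which hallucinations
are excluded from precision denominators at the tagging stage and why
document-grounded precision stays high even for weak models.

Token conflicts between claims are resolved by ranking claims longest
first, then by start offset, then by category priority; each claim
takes the still-unclaimed tokens under its span. A longer claim
therefore never loses tokens to a shorter one, and adding a
document-grounded entity can only grow the tagged set (a tested
monotonicity property). Runs of tokens owned by one claim are labeled
`B, I, ...` per run, which guarantees IOB validity by construction.

## Metrics

Scores are pooled over documents and categories before division (micro
averaging): per-category counts sum into the `micro avg` row, a
conservation property checked in the tests. Zero denominators yield 0
with the support column making the empty denominator visible, rather
than NaN or a dropped row. The valid-output ratio is computed over all
scored documents with missing generations counted as failures, so its
denominator is always the full document set.

## The synthetic corpus and simulator

The generator emulates the *shape* of the real corpus: documents
average 333 words (Poisson-distributed length), each planted with a
configurable number of mentions per category (default 7, giving ~21
mentions per document, matching the real corpus's ≈22 mentions per
document across ~1000 documents), a 9% test split share, and optional
cross-category overlapping twins and repeated surfaces. Filler text,
category terms and hallucination surfaces are drawn from three mutually
disjoint vocabularies whose tokens are pairwise distinct; consequently
a planted term occurs exactly where it was planted, hallucinated
surfaces never occur at all, and no partial match can fire between two
different terms. This is what makes the closed-form predictions exact:
with no overlaps, repeats or miscategorization, strategy-2 precision is
identically 1 and recall equals the emission probability; with
miscategorization rate *m*, category-level precision becomes 1 − *m*
and recall *r*(1 − *m*), while strategy 1, which ignores categories, is
unaffected.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: translation noise, offset/surface
disagreements, morphological variation between generation and document,
nested terminology (one term a substring of another), and any semantic
relationship between filler context and planted terms. Tests on
synthetic data validate the *pipeline arithmetic*, not model quality on
clinical text.

Simulated generations emit each gold mention independently, add
Poisson-many hallucinated surfaces, and serialize per variation.
Envelope corruptions reproduce the observed failure modes: unquoted
keys, dropped category fields, unclosed brackets — all recoverable by
the lenient parsers, as in real generations — and a prose refusal,
which is not recoverable and is what drives the valid-output ratio
down as the corruption rate rises (a tested monotonicity). Refusals
are ordinary records scored as-is; they legitimately lower recall.

All generation and simulation flows from explicit integer seeds;
identical seeds give byte-identical corpora and outputs.

## Problem sizes and tolerances

The test suite validates parameter recovery with 200 documents
(≈4,200 planted mentions), where the binomial standard error of a
recall estimate at *r* = 0.4 is ≈0.0076, so the ±0.03 acceptance band
is a ≈4σ margin; smaller property checks use 10–40 documents. Parser
oracle agreement runs on 1,000 generated valid inputs and fuzz
robustness on 1,000 random strings; overlap resolution is checked
against the brute-force oracle on 500 random mention sets of up to 20
mentions. These sizes were chosen so the entire suite runs in a few
minutes on one CPU while keeping sampling error far from every
threshold tested.

## Known limitations

- Matching is purely lexical; a model that writes "kidney stone
  surgery" for a document's "nephrolithotomy" earns nothing.
- The partial-match rule requires a contiguous token window; gapped
  matches ("left pain" for "left lumbar pain") do not count.
- Casefolding is assumed length-preserving, true for clinical English
  but not for every script.
- Strategy 1 credits all document occurrences of a term the model
  mentioned once, which can overstate token-level recall when surfaces
  repeat; this mirrors the tag-all-occurrences evaluation rule rather
  than a package choice.
- The tolerant JSON reader resolves its dialect deterministically but
  is not a JSON5 implementation; pathological inputs parse to
  *something* rather than erroring, by design.
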