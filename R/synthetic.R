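# Default term vocabularies. Every token is unique across all three
# category lists and the hallucination list, and disjoint from the
# filler vocabulary; this guarantees that (a) a planted term never
# occurs accidentally, (b) no partial match fires between two different
# terms — the closed-form precision/recall predictions of
# expected_metrics() rest on this.
VOCAB_DEFAULT <- list(
  DISEASE = c(
    "osteoporosis", "hepatitis", "meningitis", "psoriasis", "endocarditis",
    "sarcoidosis", "hypothyroidism", "pancreatitis", "amyloidosis",
    "glomerulonephritis", "diverticulitis", "cardiomyopathy",
    "rheumatoid arthritis", "ulcerative colitis"
  ),
  SYMPTOM = c(
    "vertigo", "photophobia", "dysphagia", "pruritus", "syncope",
    "tinnitus", "hemoptysis", "paresthesia", "polyuria", "myalgia",
    "epistaxis", "palpitations", "orthostatic dizziness",
    "nocturnal diaphoresis"
  ),
  PROCEDURE = c(
    "colonoscopy", "thoracentesis", "angiography", "tracheostomy",
    "cholecystectomy", "paracentesis", "bronchoscopy", "electromyography",
    "splenectomy", "arthroscopy", "craniotomy", "lithotripsy",
    "lumbar puncture", "bone scintigraphy"
  )
)

# surfaces guaranteed absent from any generated document
HALLUC_VOCAB <- c(
  "neuroblastoma", "myelofibrosis", "keratitis", "anosmia", "otalgia",
  "rhinorrhea", "cryotherapy", "phototherapy", "dermabrasion",
  "fasciotomy", "xanthelasma", "presbycusis"
)

# neutral clinical-note filler, disjoint from all term tokens above
FILLER_VOCAB <- c(
  "patient", "remained", "during", "admission", "course", "findings",
  "were", "within", "normal", "limits", "follow", "up", "arranged",
  "clinic", "review", "noted", "stable", "condition", "over", "several",
  "days", "without", "further", "events", "care", "team", "discussed",
  "plan", "family", "daily", "progress", "monitored", "closely",
  "values", "recorded", "morning", "evening", "routine", "observations",
  "continued", "ward", "transfer", "completed", "discharge", "summary",
  "prepared", "home", "support", "services", "general", "status",
  "improved", "gradually", "tolerated", "well", "oral", "intake",
  "adequate", "rest", "encouraged"
)

#' Specification for a synthetic clinical corpus
#'
#' Describes the shape of the generated corpus: multi-paragraph
#' clinical-style documents of about `words_per_doc` words (default 333,
#' the mean document length of the source corpora), with
#' `mentions_per_doc` planted mentions of each of the three categories,
#' a controllable rate of cross-category overlapping twins (to exercise
#' overlap resolution) and of repeated surface forms.
#'
#' @param n_docs Number of documents.
#' @param words_per_doc Mean words per document (default 333).
#' @param mentions_per_doc Planted mentions per category per document.
#' @param overlap_rate Probability a planted mention receives a longer
#'   overlapping twin of another category.
#' @param repeat_rate Probability a planted surface recurs (annotated)
#'   elsewhere in the document.
#' @param test_fraction Fraction of documents assigned to the TEST
#'   split (default 0.09, mirroring a 90/1000 test share).
#' @param vocab Named list of per-category term vectors.
#' @param seed Integer seed; the corpus is fully determined by it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 50L, words_per_doc = 333,
                           mentions_per_doc = 7L, overlap_rate = 0,
                           repeat_rate = 0, test_fraction = 0.09,
                           vocab = VOCAB_DEFAULT, seed = 20260101L) {
  stopifnot(
    n_docs >= 0L, words_per_doc > 0, mentions_per_doc > 0L,
    overlap_rate >= 0, overlap_rate <= 1,
    repeat_rate >= 0, repeat_rate <= 1,
    test_fraction >= 0, test_fraction <= 1
  )
  for (k in CATEGORIES) {
    if (length(vocab[[k]] %||% character()) == 0L) {
      abort(paste0("empty vocabulary for category ", k))
    }
    if (length(vocab[[k]]) < mentions_per_doc) {
      abort(paste0("vocabulary for ", k, " smaller than mentions_per_doc"))
    }
  }
  out <- list(
    n_docs = as.integer(n_docs), words_per_doc = words_per_doc,
    mentions_per_doc = as.integer(mentions_per_doc),
    overlap_rate = overlap_rate, repeat_rate = repeat_rate,
    test_fraction = test_fraction, vocab = vocab, seed = as.integer(seed)
  )
  class(out) <- "synthetic_spec"
  out
}

#' Parameters of the LLM-output simulator
#'
#' Controls the error modes of simulated generations: how often a gold
#' mention is emitted (`recall_true`), how many hallucinated surfaces —
#' guaranteed absent from the document — are added per document
#' (`halluc_rate`, Poisson mean), how often an emitted entity gets a
#' wrong category (`miscat_rate`), how often the structured envelope is
#' corrupted (`corrupt_rate`; unquoted keys, dropped categories,
#' unclosed brackets, or a prose refusal) and how often the output is
#' truncated mid-structure (`truncate_rate`).
#'
#' @param recall_true Emission probability per gold mention.
#' @param halluc_rate Expected hallucinated entities per document.
#' @param miscat_rate Wrong-category probability per emitted entity.
#' @param corrupt_rate Envelope corruption probability (variations 2/3).
#' @param truncate_rate Mid-structure truncation probability.
#' @param seed Integer seed.
#' @return A list of class `simulator_params`.
#' @export
simulator_params <- function(recall_true = 0.4, halluc_rate = 0,
                             miscat_rate = 0, corrupt_rate = 0,
                             truncate_rate = 0, seed = 20260102L) {
  probs <- c(recall_true, miscat_rate, corrupt_rate, truncate_rate)
  stopifnot(all(probs >= 0), all(probs <= 1), halluc_rate >= 0)
  out <- list(
    recall_true = recall_true, halluc_rate = halluc_rate,
    miscat_rate = miscat_rate, corrupt_rate = corrupt_rate,
    truncate_rate = truncate_rate, seed = as.integer(seed)
  )
  class(out) <- "simulator_params"
  out
}

#' Generate a synthetic merged corpus with known ground truth
#'
#' Documents are filler text with category terms planted at recorded
#' offsets; the filler vocabulary is disjoint from all term
#' vocabularies, so a term occurs exactly where it was planted. With
#' `overlap_rate > 0`, planted mentions receive a longer overlapping
#' twin of another category (the twin extends over the following filler
#' word), producing exactly the two-member overlap clusters that
#' [resolve_overlaps()] must reduce. The result is fully determined by
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `corpus` (a `merged_corpus`, mentions
#'   already overlap-resolved), and `bookkeeping`: `planted` (all
#'   mentions before resolution, twins included), `n_planted`,
#'   `n_twin_pairs`, and `n_expected_after_resolution`
#'   (`n_planted - n_twin_pairs`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  docs <- vector("list", spec$n_docs)
  ments <- vector("list", spec$n_docs)
  n_twins <- 0L
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("syn-%04d", d)
    n_words <- max(30L, rpois(1L, spec$words_per_doc))
    words <- sample(FILLER_VOCAB, n_words, replace = TRUE)
    # candidate slots every 3 words keep a free filler word after each
    # mention (twin extension) and between mentions
    cand <- seq(2L, n_words - 2L, by = 3L)
    n_m <- spec$mentions_per_doc * length(CATEGORIES)
    terms <- unlist(lapply(CATEGORIES, function(k) {
      sample(spec$vocab[[k]], spec$mentions_per_doc)
    }))
    cats <- rep(CATEGORIES, each = spec$mentions_per_doc)
    # annotated repeats of some surfaces
    rep_idx <- which(runif(n_m) < spec$repeat_rate)
    n_slots <- n_m + length(rep_idx)
    if (n_slots > length(cand)) {
      abort("words_per_doc too small for the requested mention count")
    }
    slots <- sample(cand, n_slots)
    terms <- c(terms, terms[rep_idx])
    cats <- c(cats, cats[rep_idx])
    is_repeat <- c(rep(FALSE, n_m), rep(TRUE, length(rep_idx)))
    words[slots] <- terms
    # character offsets after joining with single spaces
    lens <- stringr::str_length(words)
    starts <- cumsum(c(0L, head(lens + 1L, -1L)))
    text <- paste(words, collapse = " ")
    m <- tibble(
      doc_id = doc_id,
      start = as.integer(starts[slots]),
      end = as.integer(starts[slots] + lens[slots]),
      surface = terms, category = cats, source = "SYNTHETIC",
      twin = FALSE
    )
    # overlapping twins: extend over the following filler word, pick a
    # different category; the twin is strictly longer so it survives
    twin_sel <- which(runif(nrow(m)) < spec$overlap_rate & !is_repeat)
    if (length(twin_sel) > 0L) {
      twins <- lapply(twin_sel, function(i) {
        slot <- slots[i]
        twin_end <- starts[slot + 1L] + lens[slot + 1L]
        other <- setdiff(CATEGORIES, m$category[i])
        tibble(
          doc_id = doc_id, start = m$start[i], end = as.integer(twin_end),
          surface = stringr::str_sub(text, m$start[i] + 1L, twin_end),
          category = sample(other, 1L), source = "SYNTHETIC", twin = TRUE
        )
      })
      m <- bind_rows(m, bind_rows(twins))
      n_twins <- n_twins + length(twin_sel)
    }
    docs[[d]] <- tibble(doc_id = doc_id, text = text)
    ments[[d]] <- m
  }
  documents <- bind_rows(docs)
  if (nrow(documents) == 0L) {
    documents <- tibble(doc_id = character(), text = character())
  }
  planted <- bind_rows(ments)
  if (is.null(planted) || nrow(planted) == 0L) {
    planted <- mutate(mention_cols(), twin = logical())
  }
  n_test <- round(spec$n_docs * spec$test_fraction)
  test_ids <- if (spec$n_docs > 0L) {
    sort(sample(documents$doc_id, n_test))
  } else {
    character()
  }
  corpus <- build_merged_corpus(
    documents, select(planted, -"twin"), test_ids
  )
  list(
    corpus = corpus,
    bookkeeping = list(
      planted = planted,
      n_planted = nrow(planted),
      n_twin_pairs = n_twins,
      n_expected_after_resolution = nrow(planted) - n_twins
    )
  )
}

#' Simulate one LLM generation for a document
#'
#' Each gold mention is emitted independently with probability
#' `recall_true`; emitted entities get a wrong category with probability
#' `miscat_rate`; `Poisson(halluc_rate)` hallucinated surfaces (absent
#' from the document by construction) are added. The entity set is then
#' serialized in the style of the requested prompt variation (free-form
#' listing / keyed list / JSON annotations). With probability
#' `corrupt_rate` one envelope corruption is applied — unquoted keys,
#' dropped category fields, an unclosed bracket, or a prose refusal —
#' and with probability `truncate_rate` the output is cut mid-structure.
#'
#' @param doc A one-row document tibble or list with `doc_id`, `text`.
#' @param gold_mentions Gold mention tibble for this document.
#' @param params A [simulator_params()].
#' @param variation Prompt variation in `1:3`.
#' @param model_id Model id recorded on the output.
#' @param seed Optional integer; when given, the call is deterministic
#'   on its own. Batch drivers seed once and leave this `NULL`.
#' @return A one-row outputs tibble.
#' @export
simulate_llm_output <- function(doc, gold_mentions, params, variation,
                                model_id = "simulated", seed = NULL) {
  stopifnot(inherits(params, "simulator_params"), variation %in% 1:3)
  if (!is.null(seed)) {
    return(withr::with_seed(
      as.integer(seed),
      simulate_llm_output(doc, gold_mentions, params, variation, model_id)
    ))
  }
  doc <- as_doc(doc)
  emitted <- gold_mentions[runif(nrow(gold_mentions)) < params$recall_true, ]
  ents <- stats::setNames(
    rep(list(character()), length(CATEGORIES)), CATEGORIES
  )
  if (nrow(emitted) > 0L) {
    flip <- runif(nrow(emitted)) < params$miscat_rate
    cat_out <- emitted$category
    for (i in which(flip)) {
      cat_out[i] <- sample(setdiff(CATEGORIES, emitted$category[i]), 1L)
    }
    for (i in seq_len(nrow(emitted))) {
      ents[[cat_out[i]]] <- c(ents[[cat_out[i]]], emitted$surface[i])
    }
  }
  n_h <- rpois(1L, params$halluc_rate)
  if (n_h > 0L) {
    hsurf <- sample(HALLUC_VOCAB, min(n_h, length(HALLUC_VOCAB)))
    hcat <- sample(CATEGORIES, length(hsurf), replace = TRUE)
    for (i in seq_along(hsurf)) {
      ents[[hcat[i]]] <- c(ents[[hcat[i]]], hsurf[i])
    }
  }
  ents <- lapply(ents, dedupe_ci)
  raw <- format_entities(ents, variation)
  meta <- list(simulated = TRUE)
  if (variation >= 2L && runif(1L) < params$corrupt_rate) {
    mode <- sample(c("unquoted", "drop_category", "unclosed", "refusal"), 1L)
    raw <- corrupt_envelope(raw, variation, mode)
    meta$corruption <- mode
  }
  if (runif(1L) < params$truncate_rate) {
    cut <- max(1L, floor(stringr::str_length(raw) * runif(1L, 0.3, 0.7)))
    raw <- stringr::str_sub(raw, 1L, cut)
    meta$truncated <- TRUE
  }
  tibble(
    doc_id = doc$doc_id, model_id = model_id,
    variation = as.integer(variation), raw = raw, meta = list(meta)
  )
}

corrupt_envelope <- function(raw, variation, mode) {
  switch(mode,
    unquoted = stringr::str_remove_all(raw, stringr::fixed("\"")),
    drop_category = if (variation == 3L) {
      stringr::str_remove_all(raw, "[,\\s]*\"category\"\\s*:\\s*\"[^\"]*\"")
    } else {
      # keyed list: strip the key names, leaving bare bracketed lists
      stringr::str_remove_all(
        raw, "(?i)(diseases|symptoms|medical procedures)\\s*:\\s*"
      )
    },
    unclosed = stringr::str_remove_all(raw, "[\\]}]+$"),
    refusal = paste0(
      "I'm sorry, but I cannot annotate this clinical note as it may ",
      "contain personal health information."
    ),
    raw
  )
}

#' Simulate generations for a whole corpus
#'
#' Seeds once from `params$seed` and simulates one generation per
#' document per requested variation, so the full set is reproducible.
#'
#' @param corpus A `merged_corpus`.
#' @param params A [simulator_params()].
#' @param variations Integer vector, subset of `1:3`.
#' @param model_id Model id recorded on the outputs.
#' @return An outputs tibble.
#' @export
simulate_outputs <- function(corpus, params, variations = 1:3,
                             model_id = "simulated") {
  stopifnot(inherits(corpus, "merged_corpus"), all(variations %in% 1:3))
  withr::with_seed(params$seed, {
    rows <- list()
    for (v in variations) {
      for (d in seq_len(nrow(corpus$documents))) {
        doc <- corpus$documents[d, ]
        gold <- filter(corpus$mentions, .data$doc_id == doc$doc_id)
        rows[[length(rows) + 1L]] <-
          simulate_llm_output(doc, gold, params, v, model_id)
      }
    }
    bind_rows(rows)
  })
}

#' Closed-form metric predictions for simulator runs
#'
#' Valid when the corpus has no overlapping twins and no repeated
#' surfaces (`overlap_rate = repeat_rate = 0`) and mentions are unique
#' single-occurrence surfaces: every emitted entity is found at exactly
#' its gold span, and hallucinations (absent from the document) are
#' never tagged. Then strategy 2 has precision `1 - miscat_rate` and
#' recall `recall_true * (1 - miscat_rate)` at category level and micro;
#' strategy 1 ignores categories, so its precision is 1 and recall
#' `recall_true` regardless of `miscat_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @param params A [simulator_params()].
#' @return A list with elements `strategy1` and `strategy2`, each with
#'   `precision` and `recall`.
#' @export
expected_metrics <- function(spec, params) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(params, "simulator_params"))
  if (spec$overlap_rate != 0 || spec$repeat_rate != 0) {
    abort(paste0(
      "expected_metrics closed forms require overlap_rate = 0 and ",
      "repeat_rate = 0"
    ))
  }
  m <- params$miscat_rate
  r <- params$recall_true
  list(
    strategy1 = list(precision = 1, recall = r),
    strategy2 = list(precision = 1 - m, recall = r * (1 - m))
  )
}

#' Simulator-driven generation backend
#'
#' Wraps the simulator as an [llm_register_backend()] backend so it can
#' stand behind the generation contract; the prompt argument is ignored
#' (the simulator works from gold annotations, not from the prompt).
#'
#' @param corpus A `merged_corpus` supplying documents and gold.
#' @param params A [simulator_params()].
#' @return A backend function.
#' @export
llm_backend_simulator <- function(corpus, params) {
  force(corpus)
  force(params)
  function(prompt, doc_id, variation) {
    doc <- filter(corpus$documents, .data$doc_id == !!doc_id)
    if (nrow(doc) == 0L) {
      return(list(raw = "", meta = list(missing = TRUE)))
    }
    gold <- filter(corpus$mentions, .data$doc_id == !!doc_id)
    # per-(doc, variation) seed derived from the params seed
    dseed <- (params$seed + sum(utf8ToInt(doc_id)) * 13L +
                as.integer(variation)) %% .Machine$integer.max
    out <- simulate_llm_output(doc, gold, params, variation, seed = dseed)
    list(raw = out$raw, meta = out$meta[[1]])
  }
}
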