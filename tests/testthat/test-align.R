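test_that("normalization casefolds, squashes whitespace, strips edge punct", {
  n <- normalize_text("Fever,  CHILLS down.")
  expect_equal(n$norm, "fever chills down")
  # offset map round-trips spans back to the raw string
  doc <- "Fever,  chills"
  nn <- normalize_text(doc)
  occ <- find_occurrences(list(doc_id = "d", text = doc), "chills")
  expect_equal(nrow(occ), 1L)
  expect_equal(stringr::str_sub(doc, occ$start + 1L, occ$end), "chills")
  # already-normal text maps to itself
  plain <- normalize_text("fever chills")
  expect_equal(plain$norm, "fever chills")
  expect_equal(plain$starts, c(0:4, NA, 6:11)) # separator maps to NA
  expect_equal(normalize_text("")$norm, "")
})

test_that("complete and partial matching follow the token-subsequence rule", {
  expect_equal(
    match_term_in_text("renal ultrasound", "had a renal ultrasound today")$kind,
    "COMPLETE"
  )
  m <- match_term_in_text("left lumbar pain", "reports lumbar pain today")
  expect_equal(m$kind, "PARTIAL")
  expect_equal(m$matched, "lumbar pain")
  expect_equal(match_term_in_text("fever", "no mention here")$kind, "NONE")
  # ceil(n/2) floor: 1 of 3 tokens is not enough
  expect_equal(
    match_term_in_text("acute renal failure", "some failure occurred")$kind,
    "NONE"
  )
  # single-token terms cannot match partially (proper subsequence rule)
  expect_equal(match_term_in_text("fevers", "fever here")$kind, "NONE")
  # stopword-only subsequences never count as partial matches
  expect_equal(
    match_term_in_text("pain in the flank", "in the morning")$kind,
    "NONE"
  )
  # matching is case-insensitive and punctuation-tolerant
  expect_equal(
    match_term_in_text("Renal Ultrasound", "a renal ultrasound, was done")$kind,
    "COMPLETE"
  )
})

test_that("find_occurrences returns all token-aligned spans greedily", {
  doc <- list(doc_id = "d", text = "fever and chills and fever")
  occ <- find_occurrences(doc, "fever")
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$start, c(0L, 21L))
  expect_equal(nrow(find_occurrences(doc, "absent")), 0L)
  # surface equal to the whole document
  whole <- find_occurrences(doc, doc$text)
  expect_equal(nrow(whole), 1L)
  expect_equal(c(whole$start, whole$end), c(0L, 26L))
  # token-boundary condition: no match inside a longer token
  expect_equal(nrow(find_occurrences(list(doc_id = "d", text = "feverish"),
                                     "fever")), 0L)
})

test_that("strategy 1 tags every document occurrence of matched terms", {
  doc <- list(doc_id = "d", text = "fever and chills and fever")
  m <- tibble::tibble(
    doc_id = "d", start = 0L, end = 5L, surface = "fever",
    category = "SYMPTOM", source = "SYNTHETIC"
  )
  # output mentions the term once: both document occurrences tagged
  iob <- strategy1_tag(doc, m, "the patient had Fever.")
  expect_equal(iob$label, c("B", "O", "O", "O", "B"))
  # no shared term: all O
  expect_true(all(strategy1_tag(doc, m, "nothing relevant")$label == "O"))
  # empty generation: all O
  expect_true(all(strategy1_tag(doc, m, "")$label == "O"))
})

test_that("strategy 1 reaches P=R=1 when the output lists all surfaces", {
  withr::local_seed(81)
  for (i in 1:10) {
    gen <- generate_corpus(synthetic_spec(
      n_docs = 1L, words_per_doc = 80, mentions_per_doc = 2L,
      seed = 400L + i
    ))
    doc <- gen$corpus$documents[1, ]
    m <- gen$corpus$mentions
    raw <- paste(m$surface, collapse = ", ")
    pred <- strategy1_tag(doc, m, raw)
    gold <- to_iob(doc, m, categorical = FALSE)
    counts <- score_iob(pred, gold, "ENTITY")
    expect_equal(sum(counts$fp), 0L)
    expect_equal(sum(counts$fn), 0L)
  }
})

test_that("strategy 2 tags parsed entities by category, skipping hallucinations", {
  doc <- list(doc_id = "d", text = "fever and chills today")
  p <- parse_keyed_list(
    "{diseases: [], symptoms: [fever], medical procedures: []}", "d"
  )
  iob <- strategy2_tag(doc, p)
  expect_equal(iob$label[1], "B-SYMPTOM")
  expect_true(all(iob$label[-1] == "O"))
  # hallucinated entity leaves the sequence unchanged
  p2 <- parse_keyed_list(
    "{diseases: [neuroblastoma], symptoms: [fever], medical procedures: []}",
    "d"
  )
  expect_equal(strategy2_tag(doc, p2)$label, iob$label)
})

test_that("claim conflicts resolve longest-first then by category priority", {
  doc <- list(doc_id = "d", text = "severe lumbar pain today")
  # same surface claimed as DISEASE and SYMPTOM: DISEASE priority wins
  p <- parse_keyed_list(
    "{diseases: [lumbar pain], symptoms: [lumbar pain], medical procedures: []}",
    "d"
  )
  iob <- strategy2_tag(doc, p)
  expect_equal(iob$label, c("O", "B-DISEASE", "I-DISEASE", "O"))
  # a longer entity takes the tokens before a shorter competitor
  p2 <- parse_keyed_list(
    "{diseases: [pain], symptoms: [severe lumbar pain], medical procedures: []}",
    "d"
  )
  iob2 <- strategy2_tag(doc, p2)
  expect_equal(iob2$label,
               c("B-SYMPTOM", "I-SYMPTOM", "I-SYMPTOM", "O"))
  expect_true(iob_valid(iob2$label))
})

test_that("both strategies always emit valid IOB on randomized inputs", {
  withr::local_seed(83)
  for (i in 1:30) {
    gen <- generate_corpus(synthetic_spec(
      n_docs = 1L, words_per_doc = 60, mentions_per_doc = 3L,
      overlap_rate = 0.3, repeat_rate = 0.3, seed = 600L + i
    ))
    doc <- gen$corpus$documents[1, ]
    m <- gen$corpus$mentions
    out <- simulate_llm_output(
      doc, m, simulator_params(recall_true = 0.6, halluc_rate = 2),
      variation = 2L, seed = 700L + i
    )
    expect_true(iob_valid(strategy1_tag(doc, m, out$raw)$label))
    p <- parse_keyed_list(out$raw, doc$doc_id)
    expect_true(iob_valid(strategy2_tag(doc, p)$label))
  }
})

test_that("strategy 2 is monotone in document-grounded entities", {
  withr::local_seed(84)
  for (i in 1:15) {
    gen <- generate_corpus(synthetic_spec(
      n_docs = 1L, words_per_doc = 60, mentions_per_doc = 3L,
      seed = 800L + i
    ))
    doc <- gen$corpus$documents[1, ]
    m <- gen$corpus$mentions
    subset_idx <- sample(nrow(m), nrow(m) - 1L)
    ents_small <- split(m$surface[subset_idx], m$category[subset_idx])
    ents_full <- split(m$surface, m$category)
    tagged <- function(ents) {
      p <- parse_output(format_entities(ents, 2L), 2L, doc$doc_id)
      which(strategy2_tag(doc, p)$label != "O")
    }
    expect_true(all(tagged(ents_small) %in% tagged(ents_full)))
  }
})
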