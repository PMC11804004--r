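test_that("read_standoff_tsv parses rows and skips malformed ones", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_standoff_fixture(tmp, list(
    c("d1", "SYMPTOM", 0, 5, "fever"),
    c("d1", "SYMPTOM", 10, 16, "nausea")
  ))
  m <- read_standoff_tsv(tmp, "SYMPTOM", "SYMPTEMIST")
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(0L, 10L))
  expect_equal(m$end, c(5L, 16L))
  expect_equal(m$surface, c("fever", "nausea"))
  expect_true(all(m$category == "SYMPTOM"))
  expect_true(all(m$source == "SYMPTEMIST"))

  # header-only file
  empty <- withr::local_tempfile(fileext = ".tsv")
  write_standoff_fixture(empty, list())
  expect_equal(nrow(read_standoff_tsv(empty, "DISEASE", "DISTEMIST")), 0L)

  # end < start and non-integer offsets are skipped with a warning
  bad <- withr::local_tempfile(fileext = ".tsv")
  write_standoff_fixture(bad, list(
    c("d1", "X", 10, 4, "backwards"),
    c("d1", "X", "a", "b", "letters"),
    c("d1", "X", 3, 9, "kept")
  ))
  ws <- capture_warnings(m2 <- read_standoff_tsv(bad, "DISEASE", "DISTEMIST"))
  expect_length(ws, 2L)
  expect_equal(nrow(m2), 1L)
  expect_equal(attr(m2, "skipped"), 2L)

  expect_error(read_standoff_tsv("no/such/file.tsv", "DISEASE", "DISTEMIST"))
})

test_that("read_documents reads a directory and rejects duplicate ids", {
  dir <- withr::local_tempdir()
  fixture_docs_dir(dir, list(a = "text a", b = "text b", c = "text c"))
  docs <- read_documents(dir)
  expect_equal(docs$doc_id, c("a", "b", "c"))
  expect_equal(docs$text[docs$doc_id == "b"], "text b")

  empty <- withr::local_tempdir()
  expect_equal(nrow(read_documents(empty)), 0L)
})

test_that("intersect_common_documents is an exact set intersection", {
  expect_equal(intersect_common_documents(list(c("a", "b"), c("b", "c"))), "b")
  expect_equal(
    intersect_common_documents(list(c("x", "y"), c("x", "y"))),
    c("x", "y")
  )
  expect_equal(length(intersect_common_documents(list("a", "b"))), 0L)
})

test_that("resolve_overlaps keeps the longest span of each cluster", {
  mk <- function(starts, ends, cats = "DISEASE") {
    tibble::tibble(
      doc_id = "d", start = as.integer(starts), end = as.integer(ends),
      surface = "s", category = cats, source = "SYNTHETIC"
    )
  }
  # disjoint spans pass through (sorted)
  m <- mk(c(10, 0), c(15, 5))
  expect_equal(resolve_overlaps(m)$start, c(0L, 10L))

  # pairwise overlap: longest wins
  m <- mk(c(0, 5), c(10, 20), c("DISEASE", "PROCEDURE"))
  out <- resolve_overlaps(m)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 5L)
  expect_equal(out$category, "PROCEDURE")

  # chain (0,5),(4,9),(8,15): one cluster by transitivity, keep (8,15)
  m <- mk(c(0, 4, 8), c(5, 9, 15))
  out <- resolve_overlaps(m)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(8L, 15L))

  # equal length ties: smaller start, then category priority
  m <- mk(c(2, 0), c(8, 6), c("PROCEDURE", "SYMPTOM"))
  expect_equal(resolve_overlaps(m)$category, "SYMPTOM")
  m <- mk(c(0, 0), c(6, 6), c("PROCEDURE", "SYMPTOM"))
  expect_equal(resolve_overlaps(m)$category, "SYMPTOM")
})

test_that("resolve_overlaps matches the brute-force oracle on random sets", {
  withr::local_seed(402)
  for (i in 1:120) {
    m <- random_mention_set()
    out <- resolve_overlaps(m)
    ref <- oracle_resolve_overlaps(m)
    expect_equal(out$start, ref$start)
    expect_equal(out$end, ref$end)
    expect_equal(out$category, ref$category)
    expect_false(has_overlap(out))
    # never invents mentions: output is a subset of the input
    expect_true(all(
      paste(out$start, out$end, out$category) %in%
        paste(m$start, m$end, m$category)
    ))
  }
})

test_that("build_merged_corpus restricts, merges, resolves and splits", {
  docs <- tibble::tibble(
    doc_id = c("d1", "d2"),
    text = c("fever and chills here", "biopsy was done today")
  )
  m1 <- tibble::tibble(
    doc_id = "d1", start = 0L, end = 5L, surface = "fever",
    category = "SYMPTOM", source = "SYMPTEMIST"
  )
  m2 <- tibble::tibble(
    doc_id = "d2", start = 0L, end = 6L, surface = "biopsy",
    category = "PROCEDURE", source = "MEDPROCNER"
  )
  corpus <- build_merged_corpus(docs, list(m1, m2), test_ids = "d2")
  expect_s3_class(corpus, "merged_corpus")
  expect_equal(nrow(corpus$mentions), 2L)
  expect_equal(
    corpus$split$split[match(c("d1", "d2"), corpus$split$doc_id)],
    c("TRAIN", "TEST")
  )

  # empty test ids: all TRAIN
  all_train <- build_merged_corpus(docs, list(m1, m2))
  expect_true(all(all_train$split$split == "TRAIN"))

  # unknown test id is fatal and names the offender
  expect_error(
    build_merged_corpus(docs, list(m1), test_ids = "zz"),
    "zz"
  )

  # cross-source overlap: only the longest survives
  long <- tibble::tibble(
    doc_id = "d1", start = 0L, end = 16L, surface = "fever and chills",
    category = "DISEASE", source = "DISTEMIST"
  )
  merged <- build_merged_corpus(docs, list(m1, m2, long))
  d1m <- merged$mentions[merged$mentions$doc_id == "d1", ]
  expect_equal(nrow(d1m), 1L)
  expect_equal(d1m$end, 16L)

  # documents given per release: corpus restricted to the common ids
  rel <- build_merged_corpus(
    list(docs, docs[1, ]), list(m1, m2), test_ids = character()
  )
  expect_equal(rel$documents$doc_id, "d1")
  expect_true(all(rel$mentions$doc_id == "d1"))
})

test_that("to_iob labels tokens by the midpoint rule", {
  doc <- list(doc_id = "d1", text = "fever and chills")
  m <- tibble::tibble(
    doc_id = "d1", start = 0L, end = 5L, surface = "fever",
    category = "SYMPTOM", source = "SYNTHETIC"
  )
  expect_equal(to_iob(doc, m, categorical = TRUE)$label,
               c("B-SYMPTOM", "O", "O"))
  expect_equal(to_iob(doc, m, categorical = FALSE)$label, c("B", "O", "O"))

  # no mentions: all O
  expect_true(all(to_iob(doc, m[0, ])$label == "O"))

  # two-token mention
  doc2 <- list(doc_id = "d2", text = "pain in left flank region")
  m2 <- tibble::tibble(
    doc_id = "d2", start = 8L, end = 18L, surface = "left flank",
    category = "SYMPTOM", source = "SYNTHETIC"
  )
  labs <- to_iob(doc2, m2)$label
  expect_equal(labs[3:4], c("B-SYMPTOM", "I-SYMPTOM"))
  expect_equal(sum(labs != "O"), 2L)

  # partially covered token: midpoint decides, with a warning
  m3 <- tibble::tibble(
    doc_id = "d1", start = 0L, end = 4L, surface = "feve",
    category = "SYMPTOM", source = "SYNTHETIC"
  )
  expect_warning(labs3 <- to_iob(doc, m3)$label)
  expect_equal(labs3, c("B-SYMPTOM", "O", "O"))
})

test_that("token-aligned mentions round-trip through IOB labels", {
  withr::local_seed(515)
  for (i in 1:25) {
    gen <- generate_corpus(synthetic_spec(
      n_docs = 1L, words_per_doc = 60, mentions_per_doc = 3L,
      seed = 1000L + i
    ))
    doc <- gen$corpus$documents[1, ]
    m <- gen$corpus$mentions
    iob <- to_iob(doc, m, categorical = TRUE)
    expect_true(iob_valid(iob$label))
    dec <- decode_iob(iob)
    expect_equal(dec$start, m$start)
    expect_equal(dec$end, m$end)
    expect_equal(dec$category, m$category)
  }
})

test_that("corpus_stats counts are additive over splits", {
  gen <- generate_corpus(synthetic_spec(n_docs = 12L, seed = 33L))
  st <- corpus_stats(gen$corpus)
  wide <- tidyr::pivot_wider(
    st$mention_counts,
    names_from = "split", values_from = "n", values_fill = 0L
  )
  if (!"TEST" %in% names(wide)) wide$TEST <- 0L
  expect_equal(wide$TOTAL, wide$TRAIN + wide$TEST)
  expect_equal(sum(wide$TOTAL), nrow(gen$corpus$mentions))
  expect_equal(sum(st$doc_counts$n_docs), 12L)
  expect_gt(st$mean_doc_words, 250)

  # empty corpus: all-zero table
  empty <- build_merged_corpus(
    tibble::tibble(doc_id = character(), text = character()),
    list()
  )
  st0 <- corpus_stats(empty)
  expect_equal(nrow(st0$mention_counts), 0L)
})
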