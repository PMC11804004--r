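#' Read a standoff annotation TSV
#'
#' Reads one per-category standoff annotation release in the tab-separated
#' layout used by the DisTEMIST / SympTEMIST / MedProcNER silver-standard
#' distributions: a header row, then one mention per row with columns
#' `filename`, `label`, `start_span`, `end_span`, `text`. All rows are
#' assigned the caller's canonical `category` and `source`; offsets are
#' 0-based half-open character offsets into the document text.
#'
#' Malformed rows (non-integer offsets, `end <= start`, too few fields)
#' are skipped with a warning and reported in the `skipped` attribute of
#' the result; an unreadable file is a fatal error.
#'
#' @param path Path to the TSV file.
#' @param category One of `"DISEASE"`, `"SYMPTOM"`, `"PROCEDURE"`.
#' @param source Provenance tag, one of
#'   `"DISTEMIST"`, `"SYMPTEMIST"`, `"MEDPROCNER"`, `"SYNTHETIC"`.
#' @return A mention tibble (`doc_id`, `start`, `end`, `surface`,
#'   `category`, `source`) with attribute `skipped` counting bad rows.
#' @export
read_standoff_tsv <- function(path, category, source) {
  assert_category(category)
  stopifnot(source %in% SOURCES)
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  lines <- readr::read_lines(path, locale = readr::locale(encoding = "UTF-8"))
  if (length(lines) <= 1L) {
    out <- mention_cols()
    attr(out, "skipped") <- 0L
    return(out)
  }
  rows <- stringr::str_split(lines[-1], "\t")
  skipped <- 0L
  recs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) == 1L && !nzchar(f)) next # blank line
    start <- suppressWarnings(as.integer(f[3]))
    end <- suppressWarnings(as.integer(f[4]))
    if (length(f) < 5L || is.na(start) || is.na(end) || end <= start) {
      skipped <- skipped + 1L
      warn(paste0("skipping malformed standoff row ", i + 1L, " in ", path))
      next
    }
    recs[[i]] <- tibble(
      doc_id = f[1], start = start, end = end,
      surface = paste(f[5:length(f)], collapse = "\t"),
      category = category, source = source
    )
  }
  out <- bind_rows(recs)
  if (nrow(out) == 0L) out <- mention_cols()
  attr(out, "skipped") <- skipped
  out
}

#' Read a directory of clinical case documents
#'
#' One UTF-8 `.txt` file per document; the file stem is the document id.
#'
#' @param dir Directory path.
#' @return A tibble with columns `doc_id`, `text`, sorted by `doc_id`.
#' @export
read_documents <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("document directory not found: ", dir))
  }
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  ids <- stringr::str_remove(basename(files), "\\.txt$")
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate document ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  texts <- vapply(files, function(f) {
    txt <- tryCatch(
      readr::read_file(f, locale = readr::locale(encoding = "UTF-8")),
      error = function(e) abort(paste0("cannot decode document file: ", f))
    )
    txt
  }, character(1), USE.NAMES = FALSE)
  tibble(doc_id = ids, text = texts) %>% arrange(.data$doc_id)
}

#' Intersect document id sets
#'
#' The unified corpus is restricted to the documents shared by all source
#' releases; this is the exact set intersection of their id sets.
#'
#' @param id_sets A list of character vectors of document ids.
#' @return Character vector of ids common to every set, sorted.
#' @export
intersect_common_documents <- function(id_sets) {
  stopifnot(is.list(id_sets), length(id_sets) >= 1L)
  out <- unique(id_sets[[1]])
  for (s in id_sets[-1]) out <- intersect(out, unique(s))
  sort(out)
}

#' Resolve overlapping mention spans, keeping the longest
#'
#' Overlap clusters are the connected components of the pairwise
#' character-span overlap relation (transitive closure, so a chain of
#' overlaps forms one cluster). From each cluster exactly one mention is
#' kept: the one with maximal `end - start`; ties broken by smaller
#' `start`, then by category priority DISEASE < SYMPTOM < PROCEDURE.
#' Non-overlapping mentions pass through unchanged.
#'
#' @param mentions Mention tibble for a single document.
#' @return The surviving mentions, sorted by `start`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   doc_id = "d", start = c(0L, 5L), end = c(10L, 20L),
#'   surface = c("a", "b"), category = c("DISEASE", "PROCEDURE"),
#'   source = "SYNTHETIC"
#' )
#' resolve_overlaps(m) # keeps the longer span (5, 20)
resolve_overlaps <- function(mentions) {
  if (nrow(mentions) <= 1L) {
    return(arrange(mentions, .data$start, .data$end))
  }
  if (length(unique(mentions$doc_id)) > 1L) {
    abort("resolve_overlaps expects mentions of a single document")
  }
  m <- arrange(mentions, .data$start, .data$end)
  # sweep: spans overlap iff start < running max end of the open cluster
  cluster <- integer(nrow(m))
  cid <- 0L
  max_end <- -Inf
  for (i in seq_len(nrow(m))) {
    if (m$start[i] < max_end) {
      cluster[i] <- cid
    } else {
      cid <- cid + 1L
      cluster[i] <- cid
    }
    max_end <- max(max_end, m$end[i])
  }
  m$.cluster <- cluster
  out <- m %>%
    group_by(.data$.cluster) %>%
    arrange(
      desc(.data$end - .data$start), .data$start,
      category_priority(.data$category),
      .by_group = TRUE
    ) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-".cluster") %>%
    arrange(.data$start, .data$end)
  out
}

#' Build the unified multiclass corpus
#'
#' Restricts documents to the ids common to all mention sources, merges
#' the per-source mentions, removes cross-category overlaps per document
#' via [resolve_overlaps()], and assigns the train/test split from an
#' explicit test-id list.
#'
#' Documents common to all releases are those whose text is present in
#' every release; a common document may legitimately carry no mention of
#' some category (in the source corpora, 250 of the 1000 shared cases
#' have no disease annotation).
#'
#' @param documents Document tibble (`doc_id`, `text`), or a list of one
#'   document tibble per source release, in which case the corpus is
#'   restricted to the intersection of their id sets.
#' @param mentions A mention tibble, or a list of mention tibbles (one
#'   per source release) that will be row-bound.
#' @param test_ids Character vector of document ids forming the test
#'   split; must be a subset of the common document ids.
#' @return An object of class `merged_corpus`: a list with tibbles
#'   `documents`, `mentions` (overlap-free) and `split`
#'   (`doc_id`, `split` in `{"TRAIN","TEST"}`).
#' @export
build_merged_corpus <- function(documents, mentions, test_ids = character()) {
  if (is.list(mentions) && !is.data.frame(mentions)) {
    mentions <- bind_rows(mentions)
  }
  if (nrow(mentions) == 0L) mentions <- mention_cols()
  if (is.list(documents) && !is.data.frame(documents)) {
    common <- intersect_common_documents(lapply(documents, `[[`, "doc_id"))
    documents <- bind_rows(documents) %>%
      distinct(.data$doc_id, .keep_all = TRUE)
  } else {
    common <- unique(documents$doc_id)
  }
  missing_test <- setdiff(test_ids, common)
  if (length(missing_test) > 0L) {
    abort(paste0(
      "test ids absent from the common documents: ",
      paste(missing_test, collapse = ", ")
    ))
  }
  documents <- filter(documents, .data$doc_id %in% common)
  mentions <- filter(mentions, .data$doc_id %in% common)
  bad <- mentions %>%
    left_join(documents, by = "doc_id") %>%
    filter(.data$start < 0L | .data$end > stringr::str_length(.data$text))
  if (nrow(bad) > 0L) {
    abort(paste0(nrow(bad), " mention(s) fall outside their document text"))
  }
  # surface/offset disagreement: trust offsets, keep the mention, warn
  chk <- mentions %>% left_join(documents, by = "doc_id")
  if (nrow(chk) > 0L) {
    slice_txt <- stringr::str_sub(chk$text, chk$start + 1L, chk$end)
    mism <- squash_ws(slice_txt) != squash_ws(chk$surface)
    if (any(mism)) {
      warn(paste0(
        sum(mism), " mention surface(s) disagree with the text slice; ",
        "offsets are trusted"
      ))
    }
  }
  mentions <- if (nrow(mentions) == 0L) {
    mention_cols()
  } else {
    split(mentions, factor(mentions$doc_id, unique(mentions$doc_id))) %>%
      lapply(resolve_overlaps) %>%
      bind_rows() %>%
      select(dplyr::all_of(names(mention_cols()))) %>%
      arrange(.data$doc_id, .data$start)
  }
  corpus <- list(
    documents = documents,
    mentions = mentions,
    split = tibble(
      doc_id = documents$doc_id,
      split = ifelse(documents$doc_id %in% test_ids, "TEST", "TRAIN")
    )
  )
  class(corpus) <- "merged_corpus"
  corpus
}

squash_ws <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

#' @export
print.merged_corpus <- function(x, ...) {
  cat(
    "<merged_corpus> ", nrow(x$documents), " documents, ",
    nrow(x$mentions), " mentions (",
    sum(x$split$split == "TEST"), " test / ",
    sum(x$split$split == "TRAIN"), " train documents)\n",
    sep = ""
  )
  invisible(x)
}

#' Summary statistics of a merged corpus
#'
#' Mention counts per (source, category, split) with totals, document
#' counts per split, and mean whitespace-token document length.
#'
#' @param corpus A `merged_corpus`.
#' @return A list of class `corpus_stats` with `mention_counts`,
#'   `doc_counts`, and `mean_doc_words`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "merged_corpus"))
  m <- left_join(corpus$mentions, corpus$split, by = "doc_id")
  counts <- m %>%
    mutate(split = as.character(.data$split)) %>%
    dplyr::count(.data$source, .data$category, .data$split, name = "n")
  totals <- counts %>%
    group_by(.data$source, .data$category) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(split = "TOTAL")
  mention_counts <- bind_rows(counts, totals) %>%
    arrange(.data$source, .data$category, .data$split)
  doc_counts <- corpus$split %>% dplyr::count(.data$split, name = "n_docs")
  wlen <- if (nrow(corpus$documents) == 0L) {
    NA_real_
  } else {
    mean(stringr::str_count(corpus$documents$text, "\\S+"))
  }
  out <- list(
    mention_counts = mention_counts,
    doc_counts = doc_counts,
    mean_doc_words = wlen
  )
  class(out) <- "corpus_stats"
  out
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats> mean document length:",
      round(x$mean_doc_words, 1), "words\n")
  print(tidyr::pivot_wider(
    x$mention_counts,
    names_from = "split", values_from = "n", values_fill = 0L
  ))
  invisible(x)
}
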