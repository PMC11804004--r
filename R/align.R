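#' Match a term against a text, complete or partial
#'
#' Both term and text are normalized (casefolded, whitespace collapsed,
#' edge punctuation stripped). The match is `COMPLETE` when the
#' normalized term occurs in the normalized text at token boundaries.
#' Otherwise it is `PARTIAL` when a proper contiguous subsequence of the
#' term's tokens, of length at least `ceil(n_tokens / 2)` and containing
#' at least one non-stopword token, occurs at token boundaries (the
#' longest, then leftmost, qualifying subsequence is chosen). Otherwise
#' `NONE`. There is no stemming and no fuzzy edit-distance matching.
#'
#' @param term A non-empty entity string.
#' @param text The text to search (a document, or a raw generation).
#' @return A list with `kind` (`"COMPLETE"`, `"PARTIAL"` or `"NONE"`)
#'   and `matched` (the normalized string that was found, or `NA`).
#' @export
#' @examples
#' match_term_in_text("left lumbar pain", "reports lumbar pain today")
match_term_in_text <- function(term, text) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  match_term_norm(term, normalize_text(text))
}

# same, against a precomputed ner_norm (hot path of the taggers)
match_term_norm <- function(term, nrm) {
  term_n <- normalize_text(term)$norm
  if (!nzchar(term_n) || !nzchar(nrm$norm)) {
    return(list(kind = "NONE", matched = NA_character_))
  }
  if (length(norm_occurrences(nrm, term_n)) > 0L) {
    return(list(kind = "COMPLETE", matched = term_n))
  }
  toks <- stringr::str_split(term_n, stringr::fixed(" "))[[1]]
  n <- length(toks)
  if (n < 2L) {
    return(list(kind = "NONE", matched = NA_character_))
  }
  min_len <- ceiling(n / 2)
  for (len in seq(n - 1L, min_len)) {
    for (i in seq_len(n - len + 1L)) {
      window <- toks[i:(i + len - 1L)]
      if (!any(!(window %in% STOPWORDS))) next
      cand <- paste(window, collapse = " ")
      if (length(norm_occurrences(nrm, cand)) > 0L) {
        return(list(kind = "PARTIAL", matched = cand))
      }
    }
  }
  list(kind = "NONE", matched = NA_character_)
}

#' Find all occurrences of a surface form in a document
#'
#' All non-overlapping, token-boundary-aligned occurrences of the
#' normalized surface in the normalized document text, mapped back to
#' raw character offsets (0-based, half-open). Selection is
#' left-to-right greedy.
#'
#' @param doc A one-row document tibble or list with `doc_id`, `text`.
#' @param surface A non-empty string.
#' @return A tibble with columns `start`, `end` (raw character offsets).
#' @export
find_occurrences <- function(doc, surface) {
  doc <- as_doc(doc)
  stopifnot(nzchar(surface))
  occurrences_norm(normalize_text(doc$text), normalize_text(surface)$norm)
}

occurrences_norm <- function(nrm, needle_norm) {
  out <- tibble(start = integer(), end = integer())
  if (!nzchar(needle_norm)) {
    return(out)
  }
  pos <- norm_occurrences(nrm, needle_norm)
  if (length(pos) == 0L) {
    return(out)
  }
  n <- stringr::str_length(needle_norm)
  spans <- vapply(pos, function(p) norm_span_to_raw(nrm, p, p + n),
                  numeric(2))
  tibble(start = as.integer(spans[1, ]), end = as.integer(spans[2, ]))
}

# Assign claimed character spans to document tokens and emit IOB labels.
# Claims are ranked longest-first, then by start, then by category
# priority; each claim takes the still-unclaimed tokens whose midpoint
# falls inside its span (so a longer claim never loses tokens to a
# shorter one). Contiguous runs of tokens owned by the same claim are
# labeled B, I...; this always yields a valid IOB sequence.
apply_claims <- function(doc, claims, categorical) {
  doc <- as_doc(doc)
  toks <- tokenize_text(doc$text)
  labels <- rep("O", nrow(toks))
  if (nrow(claims) > 0L && nrow(toks) > 0L) {
    claims <- claims %>%
      distinct(.data$start, .data$end, .data$category) %>%
      arrange(
        desc(.data$end - .data$start), .data$start,
        category_priority(.data$category)
      )
    mid <- (toks$start + toks$end) / 2
    owner <- rep(NA_integer_, nrow(toks))
    for (i in seq_len(nrow(claims))) {
      inside <- which(mid > claims$start[i] & mid < claims$end[i] &
                        is.na(owner))
      owner[inside] <- i
    }
    for (i in unique(owner[!is.na(owner)])) {
      idx <- which(owner == i)
      tag <- if (categorical) paste0("-", claims$category[i]) else ""
      runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      for (r in runs) {
        labels[r[1]] <- paste0("B", tag)
        if (length(r) > 1L) labels[r[-1]] <- paste0("I", tag)
      }
    }
  }
  tibble(
    doc_id = doc$doc_id, token = toks$token,
    start = toks$start, end = toks$end, label = labels
  )
}

#' Tag a document under evaluation strategy 1 (category-blind)
#'
#' Strategy 1 asks only whether the model's generation mentions each
#' silver-standard term, in any output format. For every distinct silver
#' surface form that matches the generation text (complete or partial),
#' every occurrence of the matched string in the document is tagged with
#' bare `B`/`I` tags; all other tokens are `O`. For a partial match, the
#' occurrences tagged are those of the matched token subsequence, not of
#' the full term (tagging unmatched tokens would fabricate evidence).
#' Overlapping claims are resolved longest-first.
#'
#' @param doc A one-row document tibble or list with `doc_id`, `text`.
#' @param mentions Silver mention tibble for this document.
#' @param raw The raw generation text (or an outputs tibble row's `raw`).
#' @return A binary IOB tibble (`doc_id`, `token`, `start`, `end`,
#'   `label`).
#' @export
strategy1_tag <- function(doc, mentions, raw) {
  doc <- as_doc(doc)
  if (length(raw) == 1L && is.list(raw)) raw <- raw$raw
  raw <- as.character(raw %||% "")
  if (is.na(raw)) raw <- ""
  surfaces <- unique(mentions$surface)
  nrm_out <- normalize_text(raw)
  nrm_doc <- normalize_text(doc$text)
  claims <- list()
  for (s in surfaces) {
    if (!nzchar(s)) next
    m <- match_term_norm(s, nrm_out)
    if (m$kind == "NONE") next
    occ <- occurrences_norm(nrm_doc, m$matched)
    if (nrow(occ) > 0L) {
      claims[[length(claims) + 1L]] <- mutate(occ, category = NA_character_)
    }
  }
  claims <- if (length(claims)) bind_rows(claims) else
    tibble(start = integer(), end = integer(), category = character())
  apply_claims(doc, claims, categorical = FALSE)
}

#' Tag a document under evaluation strategy 2 (categorical)
#'
#' Strategy 2 scores the entities recovered from the requested output
#' structure. For each category and each parsed entity that matches the
#' document text (complete or partial), all occurrences of the matched
#' string are tagged with that category's `B`/`I` tags. Entities with no
#' occurrence in the document — hallucinations — contribute nothing,
#' which is why document-grounded matching keeps precision high even for
#' weak models. Token conflicts are resolved longest-entity-first, then
#' by category priority.
#'
#' @param doc A one-row document tibble or list with `doc_id`, `text`.
#' @param parsed A `parsed_entities` object for this document.
#' @return A categorical IOB tibble.
#' @export
strategy2_tag <- function(doc, parsed) {
  doc <- as_doc(doc)
  stopifnot(inherits(parsed, "parsed_entities"))
  nrm_doc <- normalize_text(doc$text)
  claims <- list()
  for (k in CATEGORIES) {
    for (e in parsed$entities[[k]]) {
      if (!nzchar(e)) next
      m <- match_term_norm(e, nrm_doc)
      if (m$kind == "NONE") next
      occ <- occurrences_norm(nrm_doc, m$matched)
      if (nrow(occ) > 0L) {
        claims[[length(claims) + 1L]] <- mutate(occ, category = k)
      }
    }
  }
  claims <- if (length(claims)) bind_rows(claims) else
    tibble(start = integer(), end = integer(), category = character())
  apply_claims(doc, claims, categorical = TRUE)
}
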