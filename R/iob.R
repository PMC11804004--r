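#' Convert a document and its mentions to IOB labels
#'
#' Tokens come from [tokenize_text()]. A token belongs to a mention iff
#' its span midpoint falls inside the mention's character span (this also
#' covers fully contained tokens, and resolves silver offsets that cut a
#' token deterministically); the first such token gets `B`, subsequent
#' ones `I`, everything else `O`. With `categorical = TRUE` tags carry
#' the category (`B-DISEASE`, ...), otherwise bare `B`/`I`.
#'
#' @param doc A one-row document tibble or a list with `doc_id`, `text`.
#' @param mentions Non-overlapping mention tibble for this document.
#' @param categorical Carry categories on the tags? Default `TRUE`.
#' @return An IOB tibble with columns `doc_id`, `token`, `start`, `end`,
#'   `label`.
#' @export
#' @examples
#' doc <- list(doc_id = "d1", text = "fever and chills")
#' m <- tibble::tibble(
#'   doc_id = "d1", start = 0L, end = 5L, surface = "fever",
#'   category = "SYMPTOM", source = "SYNTHETIC"
#' )
#' to_iob(doc, m)
to_iob <- function(doc, mentions, categorical = TRUE) {
  doc <- as_doc(doc)
  toks <- tokenize_text(doc$text)
  labels <- rep("O", nrow(toks))
  if (nrow(mentions) > 0L) {
    mentions <- arrange(mentions, .data$start)
    if (any(mentions$end[-nrow(mentions)] > mentions$start[-1] &
            nrow(mentions) > 1L)) {
      abort("to_iob requires non-overlapping mentions")
    }
    mid <- (toks$start + toks$end) / 2
    for (i in seq_len(nrow(mentions))) {
      inside <- which(mid > mentions$start[i] & mid < mentions$end[i])
      partial <- inside[toks$start[inside] < mentions$start[i] |
                          toks$end[inside] > mentions$end[i]]
      if (length(partial) > 0L) {
        warn(paste0(
          "mention (", mentions$start[i], ",", mentions$end[i],
          ") in ", doc$doc_id, " crosses token boundaries; ",
          "midpoint rule applied"
        ))
      }
      if (length(inside) == 0L) next
      tag <- if (categorical) paste0("-", mentions$category[i]) else ""
      labels[inside[1]] <- paste0("B", tag)
      if (length(inside) > 1L) {
        labels[inside[-1]] <- paste0("I", tag)
      }
    }
  }
  tibble(
    doc_id = doc$doc_id, token = toks$token,
    start = toks$start, end = toks$end, label = labels
  )
}

#' Decode an IOB tibble back into mention spans
#'
#' Each maximal `B` (+ following `I` of the same category) run becomes
#' one mention spanning from the first token's start to the last token's
#' end. Binary tags decode with `category = NA`.
#'
#' @param iob An IOB tibble as produced by [to_iob()] (single document).
#' @return A tibble with columns `doc_id`, `start`, `end`, `category`.
#' @export
decode_iob <- function(iob) {
  out <- tibble(
    doc_id = character(), start = integer(), end = integer(),
    category = character()
  )
  n <- nrow(iob)
  if (n == 0L) {
    return(out)
  }
  pre <- stringr::str_sub(iob$label, 1, 1)
  cat_of <- ifelse(
    stringr::str_detect(iob$label, "-"),
    stringr::str_remove(iob$label, "^[BI]-"),
    NA_character_
  )
  recs <- list()
  i <- 1L
  while (i <= n) {
    if (pre[i] == "B") {
      j <- i
      while (j + 1L <= n && pre[j + 1L] == "I" &&
             identical(cat_of[j + 1L], cat_of[i])) {
        j <- j + 1L
      }
      recs[[length(recs) + 1L]] <- tibble(
        doc_id = iob$doc_id[i], start = iob$start[i], end = iob$end[j],
        category = cat_of[i]
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(recs) == 0L) out else bind_rows(recs)
}

#' Check IOB label-transition validity
#'
#' `TRUE` iff the label sequence satisfies the IOB transition rules: no
#' `I` at position 0, after `O`, or after a tag of a different category.
#'
#' @param labels Character vector of IOB labels.
#' @return A logical scalar.
#' @export
iob_valid <- function(labels) {
  if (length(labels) == 0L) {
    return(TRUE)
  }
  pre <- stringr::str_sub(labels, 1, 1)
  cats <- ifelse(
    stringr::str_detect(labels, "-"),
    stringr::str_remove(labels, "^[BI]-"), ""
  )
  for (i in seq_along(labels)) {
    if (pre[i] == "I") {
      if (i == 1L || pre[i - 1L] == "O" || cats[i - 1L] != cats[i]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

as_doc <- function(doc) {
  if (is.data.frame(doc)) {
    stopifnot(nrow(doc) == 1L)
    doc <- as.list(doc)
  }
  stopifnot(!is.null(doc$doc_id), !is.null(doc$text))
  doc
}

#' Write IOB labels as a CoNLL-style file
#'
#' Token-per-line `token TAB tag`, with a `# doc_id = <id>` comment line
#' before each document and a blank line between documents.
#'
#' @param iob IOB tibble, possibly covering several documents.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(iob, path) {
  blocks <- lapply(split(iob, factor(iob$doc_id, unique(iob$doc_id))),
    function(d) {
      c(paste0("# doc_id = ", d$doc_id[1]),
        paste0(d$token, "\t", d$label), "")
    }
  )
  readr::write_lines(unlist(blocks), path)
  invisible(path)
}

#' Write mentions as JSONL
#'
#' One mention object per line with keys `doc_id`, `start`, `end`,
#' `surface`, `category`, `source`.
#'
#' @param mentions Mention tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions_jsonl <- function(mentions, path) {
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    jsonlite::toJSON(as.list(mentions[i, ]), auto_unbox = TRUE)
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read mentions from JSONL
#'
#' @param path Path to a JSONL mention dump from [write_mentions_jsonl()].
#' @return Mention tibble.
#' @export
read_mentions_jsonl <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(mention_cols())
  }
  bind_rows(lapply(lines, function(l) {
    as_tibble(jsonlite::fromJSON(l))
  })) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}
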