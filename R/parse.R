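#' Canonicalize a category label
#'
#' Case- and plural-insensitive mapping of model-emitted category names
#' onto the three canonical categories. Anything else (e.g. a model
#' answering `"not applicable"`) maps to `NA`: entities with
#' non-canonical categories are dropped rather than reassigned, since
#' guessing a category would inject evaluator bias.
#'
#' @param label A category string as emitted by a model.
#' @return One of `"DISEASE"`, `"SYMPTOM"`, `"PROCEDURE"`, or
#'   `NA_character_`.
#' @export
#' @examples
#' canonicalize_category("Diseases")
#' canonicalize_category("medical procedure")
#' canonicalize_category("not applicable")
canonicalize_category <- function(label) {
  if (length(label) == 0L || is.null(label)) {
    return(NA_character_)
  }
  x <- stringr::str_to_lower(stringr::str_squish(as.character(label[[1]])))
  x <- stringr::str_remove_all(x, "[\"'“”‘’]")
  x <- stringr::str_remove(x, "s$")
  switch(x,
    "disease" = "DISEASE",
    "symptom" = "SYMPTOM",
    "medical procedure" = "PROCEDURE",
    "procedure" = "PROCEDURE",
    NA_character_
  )
}

new_parsed <- function(doc_id, variation, entities, status, diagnostics,
                       n_objects = NA_integer_) {
  ents <- stats::setNames(
    lapply(CATEGORIES, function(k) as.character(entities[[k]] %||% character())),
    CATEGORIES
  )
  out <- list(
    doc_id = doc_id, variation = as.integer(variation),
    entities = ents, status = status,
    diagnostics = as.character(diagnostics),
    n_objects = n_objects
  )
  class(out) <- "parsed_entities"
  out
}

#' @export
print.parsed_entities <- function(x, ...) {
  cat("<parsed_entities> status:", x$status, "\n")
  for (k in CATEGORIES) {
    cat(" ", k, ": ", paste(x$entities[[k]], collapse = "; "), "\n", sep = "")
  }
  if (length(x$diagnostics)) {
    cat("  diagnostics:", length(x$diagnostics), "\n")
  }
  invisible(x)
}

#' Did a generation parse into at least one canonical entity?
#'
#' The valid-output ratio counts a document as correctly parsed iff its
#' generation yielded at least one entity in the requested structure,
#' i.e. status `PARSED`.
#'
#' @param p A `parsed_entities` object.
#' @return `TRUE` or `FALSE`.
#' @export
parsed_ok <- function(p) {
  stopifnot(inherits(p, "parsed_entities"))
  identical(p$status, "PARSED")
}

# trims an item string: whitespace, bullets/numbering, wrapping quotes,
# trailing punctuation
clean_item <- function(x) {
  x <- stringr::str_trim(x)
  x <- stringr::str_remove(x, "^(?:[-*•·]+\\s+|\\d+[.)]\\s+)+")
  x <- stringr::str_remove_all(x, "^[\"'“‘]|[\"'”’]$")
  x <- stringr::str_remove(x, "[.,;:]+$")
  stringr::str_trim(x)
}

# split on ; , and newlines at zero bracket/paren depth
split_items <- function(content) {
  chars <- stringr::str_split(content, "")[[1]]
  depth <- 0L
  items <- character()
  buf <- character()
  for (ch in chars) {
    if (ch %in% c("(", "[", "{")) depth <- depth + 1L
    if (ch %in% c(")", "]", "}")) depth <- max(0L, depth - 1L)
    if (depth == 0L && ch %in% c(";", ",", "\n")) {
      items <- c(items, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  items <- c(items, paste(buf, collapse = ""))
  items <- vapply(items, clean_item, character(1), USE.NAMES = FALSE)
  items[nzchar(items)]
}

dedupe_ci <- function(x) x[!duplicated(stringr::str_to_lower(x))]

#' Parse a keyed-list generation (prompt variation 2)
#'
#' Recovers per-category entity lists from the Python-dictionary-like
#' structure requested by prompt variation 2, tolerating the dialects
#' models actually produce: keys with or without braces, bullets or
#' asterisks; bracketed lists, possibly unterminated; bracketless
#' line-delimited lists (accepted with a diagnostic); items separated by
#' semicolons, commas or newlines. Items are trimmed of whitespace,
#' bullets and trailing punctuation and deduplicated case-insensitively,
#' keeping first occurrence. When a generation restates the structure,
#' the first occurrence of each category key wins. Never raises.
#'
#' @param raw Arbitrary generation text.
#' @param doc_id,variation Provenance carried on the result.
#' @return A `parsed_entities` object with status `PARSED`, `EMPTY` or
#'   `UNPARSEABLE`.
#' @export
parse_keyed_list <- function(raw, doc_id = NA_character_, variation = 2L) {
  diagnostics <- character()
  empty <- stats::setNames(
    rep(list(character()), length(CATEGORIES)), CATEGORIES
  )
  if (is.null(raw) || length(raw) == 0L || is.na(raw) || !nzchar(raw)) {
    return(new_parsed(doc_id, variation, empty, "UNPARSEABLE",
                      "empty generation"))
  }
  raw <- as.character(raw[[1]])
  key_pat <- paste0(
    "(?i)(medical\\s+procedures?|procedures?|diseases?|symptoms?)",
    "[\"'”’]?\\s*:"
  )
  locs <- stringr::str_locate_all(raw, key_pat)[[1]]
  if (nrow(locs) == 0L) {
    return(new_parsed(doc_id, variation, empty, "UNPARSEABLE",
                      "no category structure found"))
  }
  keys <- stringr::str_match(
    stringr::str_sub(raw, locs[, 1], locs[, 2]), "(?i)^([a-z\\s]+)"
  )[, 2]
  cats <- vapply(keys, canonicalize_category, character(1), USE.NAMES = FALSE)
  entities <- empty
  seen <- character()
  total_len <- stringr::str_length(raw)
  for (i in seq_len(nrow(locs))) {
    k <- cats[i]
    if (is.na(k) || k %in% seen) next
    seen <- c(seen, k)
    region_end <- if (i < nrow(locs)) locs[i + 1L, 1] - 1L else total_len
    region <- stringr::str_sub(raw, locs[i, 2] + 1L, region_end)
    lead <- stringr::str_match(region, "^\\s*")[1, 1]
    body <- stringr::str_sub(region, stringr::str_length(lead) + 1L)
    if (stringr::str_sub(body, 1, 1) == "[") {
      inner <- stringr::str_sub(body, 2)
      close <- find_balanced_close(inner)
      if (is.na(close)) {
        diagnostics <- c(diagnostics,
                         paste0("unterminated bracket for ", k))
        content <- inner
      } else {
        content <- stringr::str_sub(inner, 1, close - 1L)
      }
    } else {
      diagnostics <- c(diagnostics, paste0("bracketless list for ", k))
      blank <- stringr::str_locate(body, "\\n[ \\t]*\\n")[1, 1]
      content <- if (is.na(blank)) body else stringr::str_sub(body, 1, blank - 1L)
    }
    entities[[k]] <- dedupe_ci(split_items(content))
  }
  status <- if (any(lengths(entities) > 0L)) "PARSED" else "EMPTY"
  new_parsed(doc_id, variation, entities, status, diagnostics)
}

# position (1-based, within `inner`) of the "]" closing a list whose "["
# has already been consumed; NA if unterminated
find_balanced_close <- function(inner) {
  chars <- stringr::str_split(inner, "")[[1]]
  depth <- 0L
  for (j in seq_along(chars)) {
    if (chars[j] == "[") depth <- depth + 1L
    if (chars[j] == "]") {
      if (depth == 0L) {
        return(j)
      }
      depth <- depth - 1L
    }
  }
  NA_integer_
}

#' Parse a JSON-annotations generation (prompt variation 3)
#'
#' Locates the first brace region carrying an `annotations` key and
#' reads it with a fault-tolerant JSON reader that accepts the malformed
#' dialects observed in real generations: unquoted keys and values,
#' typographic quotes, trailing commas, and structures truncated
#' mid-stream (unterminated brackets are closed at end of input).
#' Annotation objects must carry an `entity` and a canonical `category`;
#' objects missing either are dropped with a diagnostic. On
#' syntactically valid JSON the result coincides with a strict JSON
#' parse. Never raises.
#'
#' @inheritParams parse_keyed_list
#' @return A `parsed_entities` object; `n_objects` records how many
#'   annotation objects were recovered before category filtering.
#' @export
parse_json_annotations <- function(raw, doc_id = NA_character_,
                                   variation = 3L) {
  empty <- stats::setNames(
    rep(list(character()), length(CATEGORIES)), CATEGORIES
  )
  if (is.null(raw) || length(raw) == 0L || is.na(raw) || !nzchar(raw)) {
    return(new_parsed(doc_id, variation, empty, "UNPARSEABLE",
                      "empty generation", 0L))
  }
  raw <- as.character(raw[[1]])
  key <- stringr::str_locate(
    raw, "(?i)[\"'“”]?annotations[\"'“”]?\\s*:"
  )
  if (is.na(key[1, 1])) {
    return(new_parsed(doc_id, variation, empty, "UNPARSEABLE",
                      "no annotations structure found", 0L))
  }
  braces <- stringr::str_locate_all(stringr::str_sub(raw, 1, key[1, 1]),
                                    stringr::fixed("{"))[[1]]
  region <- if (nrow(braces) > 0L) {
    stringr::str_sub(raw, braces[nrow(braces), 1])
  } else {
    paste0("{", stringr::str_sub(raw, key[1, 1]))
  }
  obj <- tolerant_json(region)
  diagnostics <- character()
  ann <- NULL
  if (is.list(obj) && !is.null(names(obj))) {
    hit <- which(stringr::str_detect(
      stringr::str_to_lower(names(obj)), "^annotations?$"
    ))
    if (length(hit) > 0L) ann <- obj[[hit[1]]]
  }
  if (is.null(ann)) {
    return(new_parsed(doc_id, variation, empty, "UNPARSEABLE",
                      "annotations key yielded no list", 0L))
  }
  # a single annotation object instead of an array
  if (!is.null(names(ann))) ann <- list(ann)
  entities <- empty
  n_obj <- 0L
  for (item in ann) {
    if (!is.list(item) || is.null(names(item))) {
      diagnostics <- c(diagnostics, "non-object annotation entry dropped")
      next
    }
    n_obj <- n_obj + 1L
    nms <- stringr::str_to_lower(stringr::str_trim(names(item)))
    ei <- match("entity", nms)
    ci <- match("category", nms)
    ent <- if (is.na(ei)) NULL else item[[ei]]
    cat_raw <- if (is.na(ci)) NULL else item[[ci]]
    ent <- if (is.null(ent)) "" else stringr::str_trim(as.character(ent[[1]]))
    if (!nzchar(ent)) {
      diagnostics <- c(diagnostics, "annotation missing entity dropped")
      next
    }
    if (is.null(cat_raw)) {
      diagnostics <- c(diagnostics,
                       paste0("annotation missing category: ", ent))
      next
    }
    k <- canonicalize_category(cat_raw)
    if (is.na(k)) {
      diagnostics <- c(diagnostics, paste0(
        "non-canonical category '", as.character(cat_raw[[1]]), "': ", ent
      ))
      next
    }
    entities[[k]] <- dedupe_ci(c(entities[[k]], clean_item(ent)))
  }
  status <- if (any(lengths(entities) > 0L)) "PARSED" else "EMPTY"
  new_parsed(doc_id, variation, entities, status, diagnostics, n_obj)
}

#' Parse one generation according to its prompt variation
#'
#' Dispatches to [parse_keyed_list()] for variation 2 and
#' [parse_json_annotations()] for variation 3. Variation 1 requests no
#' structure; its outputs are parsed with the keyed-list reader, which
#' also understands free-form category headings.
#'
#' @param raw Generation text.
#' @param variation Prompt variation in `1:3`.
#' @param doc_id Document id carried on the result.
#' @return A `parsed_entities` object.
#' @export
parse_output <- function(raw, variation, doc_id = NA_character_) {
  if (as.integer(variation) == 3L) {
    parse_json_annotations(raw, doc_id, variation)
  } else {
    parse_keyed_list(raw, doc_id, variation)
  }
}

#' Re-serialize a parsed entity set into the canonical requested format
#'
#' Variation 2 yields the keyed-list structure, variation 3 the JSON
#' annotations structure, variation 1 a free-form bulleted listing.
#' Re-parsing the serialization recovers the same entity set
#' (round-trip idempotence).
#'
#' @param entities Named list of character vectors keyed by category
#'   (as in a `parsed_entities` object), or a `parsed_entities` object.
#' @param variation Prompt variation in `1:3`.
#' @return A single string.
#' @export
format_entities <- function(entities, variation) {
  if (inherits(entities, "parsed_entities")) entities <- entities$entities
  ents <- lapply(CATEGORIES, function(k) {
    as.character(entities[[k]] %||% character())
  })
  names(ents) <- CATEGORIES
  variation <- as.integer(variation)
  if (variation == 2L) {
    part <- function(key, v) paste0(key, ": [", paste(v, collapse = "; "), "]")
    return(paste0(
      "{", part("diseases", ents$DISEASE), ", ",
      part("symptoms", ents$SYMPTOM), ", ",
      part("medical procedures", ents$PROCEDURE), "}"
    ))
  }
  if (variation == 3L) {
    label <- c(
      DISEASE = "disease", SYMPTOM = "symptom", PROCEDURE = "medical procedure"
    )
    ann <- list()
    for (k in CATEGORIES) {
      for (e in ents[[k]]) {
        ann[[length(ann) + 1L]] <- list(entity = e, category = label[[k]])
      }
    }
    return(as.character(jsonlite::toJSON(
      list(annotations = ann), auto_unbox = TRUE
    )))
  }
  heading <- c(
    DISEASE = "Diseases:", SYMPTOM = "Symptoms:",
    PROCEDURE = "Medical procedures:"
  )
  blocks <- vapply(CATEGORIES, function(k) {
    paste0(heading[[k]], "\n",
           paste0("- ", ents[[k]], collapse = "\n"))
  }, character(1))
  paste(blocks, collapse = "\n")
}
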