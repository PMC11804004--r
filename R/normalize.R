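#' Normalize text for matching, keeping an offset map
#'
#' Matching between model output strings and document text is done on a
#' normalized view: casefolded, whitespace runs collapsed to single
#' spaces, and punctuation stripped from the edges of each token.
#' The offset map translates positions in the normalized string back to
#' character offsets in the raw string, so matched spans can be tagged
#' at their original location.
#'
#' @param text A single string.
#' @return A list of class `ner_norm` with elements:
#'   * `norm`: the normalized string,
#'   * `starts`: integer vector, for each normalized character the 0-based
#'     raw offset it came from (`NA` for inserted separator spaces),
#'   * `token_starts`, `token_ends`: 0-based positions in `norm` where
#'     tokens begin / end (half-open), defining the legal match boundaries.
#' @export
#' @examples
#' normalize_text("Fever,  CHILLS.")$norm
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  res <- list(
    norm = "", starts = integer(),
    token_starts = integer(), token_ends = integer()
  )
  class(res) <- "ner_norm"
  if (is.na(text) || !nzchar(text)) {
    return(res)
  }
  loc <- stringr::str_locate_all(text, "\\S+")[[1]]
  if (nrow(loc) == 0L) {
    return(res)
  }
  chunks <- stringr::str_sub(text, loc[, 1], loc[, 2])
  m <- stringr::str_match(chunks, "^(\\p{P}*)(.*?)(\\p{P}*)$")
  cores <- m[, 3]
  keep <- nzchar(cores)
  if (!any(keep)) {
    return(res)
  }
  cores <- cores[keep]
  core_start0 <- (loc[keep, 1] - 1L) + stringr::str_length(m[keep, 2])
  cores_lc <- stringr::str_to_lower(cores)
  # casefolding is assumed length-preserving (true for clinical English)
  bad <- stringr::str_length(cores_lc) != stringr::str_length(cores)
  if (any(bad)) {
    cores_lc[bad] <- cores[bad]
  }
  lens <- stringr::str_length(cores_lc)
  n_tok <- length(cores_lc)
  norm <- paste(cores_lc, collapse = " ")
  tok_start_norm <- c(0L, cumsum(lens + 1L)[-n_tok])
  tok_end_norm <- tok_start_norm + lens
  starts <- rep(NA_integer_, stringr::str_length(norm))
  within_tok <- sequence(lens) - 1L
  idx <- rep(tok_start_norm, lens) + within_tok + 1L
  starts[idx] <- as.integer(rep(core_start0, lens) + within_tok)
  res$norm <- norm
  res$starts <- starts
  res$token_starts <- as.integer(tok_start_norm)
  res$token_ends <- as.integer(tok_end_norm)
  res
}

# Map a normalized half-open span [a, b) back to raw character offsets.
norm_span_to_raw <- function(nrm, a, b) {
  stopifnot(b > a)
  raw_start <- nrm$starts[a + 1L]
  raw_end <- nrm$starts[b] + 1L
  c(start = raw_start, end = raw_end)
}

# All non-overlapping token-boundary-aligned occurrences of a normalized
# needle in a ner_norm object; returns 0-based normalized start positions,
# left-to-right greedy.
norm_occurrences <- function(nrm, needle) {
  n <- stringr::str_length(needle)
  if (n == 0L || !nzchar(nrm$norm)) {
    return(integer())
  }
  cand <- nrm$token_starts[nrm$token_starts + n <= stringr::str_length(nrm$norm) + 0L]
  cand <- cand[(cand + n) %in% nrm$token_ends]
  if (length(cand) == 0L) {
    return(integer())
  }
  hit <- stringr::str_sub(nrm$norm, cand + 1L, cand + n) == needle
  cand <- cand[hit]
  if (length(cand) <= 1L) {
    return(cand)
  }
  # greedy non-overlapping selection
  keep <- integer()
  last_end <- -1L
  for (p in cand) {
    if (p >= last_end) {
      keep <- c(keep, p)
      last_end <- p + n
    }
  }
  keep
}
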