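#' Offset-preserving tokenizer
#'
#' Splits text on whitespace and then peels leading/trailing punctuation
#' characters off each chunk into tokens of their own, so that mention
#' boundaries from standoff annotation stay token-aligned ("(fever)."
#' becomes `(`, `fever`, `)`, `.`). Internal hyphens and dashes are kept
#' ("night-time" is one token). Offsets are 0-based, half-open, counted
#' in characters of the input string.
#'
#' @param text A single string.
#' @return A tibble with columns `token`, `start`, `end`.
#' @export
#' @examples
#' tokenize_text("Fever, chills.")
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(token = character(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  loc <- stringr::str_locate_all(text, "\\S+")[[1]]
  if (nrow(loc) == 0L) {
    return(empty)
  }
  chunks <- stringr::str_sub(text, loc[, 1], loc[, 2])
  chunk_start0 <- loc[, 1] - 1L
  m <- stringr::str_match(chunks, "^(\\p{P}*)(.*?)(\\p{P}*)$")
  plain <- !nzchar(m[, 2]) & !nzchar(m[, 4]) & nzchar(m[, 3])
  if (all(plain)) {
    return(tibble(
      token = chunks,
      start = as.integer(chunk_start0),
      end = as.integer(chunk_start0 + stringr::str_length(chunks))
    ))
  }
  toks <- vector("list", length(chunks))
  starts <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    if (plain[i]) {
      toks[[i]] <- chunks[i]
      starts[[i]] <- chunk_start0[i]
      next
    }
    core <- m[i, 3]
    if (!nzchar(core)) {
      # all-punctuation chunk: one token per character
      chars <- stringr::str_split(chunks[i], "")[[1]]
      toks[[i]] <- chars
      starts[[i]] <- chunk_start0[i] + seq_along(chars) - 1L
      next
    }
    pre <- if (nzchar(m[i, 2])) stringr::str_split(m[i, 2], "")[[1]] else character()
    post <- if (nzchar(m[i, 4])) stringr::str_split(m[i, 4], "")[[1]] else character()
    tk <- c(pre, core, post)
    off <- cumsum(c(0L, stringr::str_length(tk)))
    toks[[i]] <- tk
    starts[[i]] <- chunk_start0[i] + off[seq_along(tk)]
  }
  token <- unlist(toks, use.names = FALSE)
  start <- as.integer(unlist(starts, use.names = FALSE))
  tibble(
    token = token, start = start,
    end = as.integer(start + stringr::str_length(token))
  )
}
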