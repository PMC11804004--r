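# A fault-tolerant JSON reader for LLM generations.
#
# Accepts, beyond strict JSON: unquoted keys and bareword values
# ("entity: sub-Saharan origin"), typographic quotes, trailing commas,
# and truncated structures (end of input closes every open bracket).
# On strictly valid JSON input it reads the same structure a strict
# parser does (objects -> named lists, arrays -> unnamed lists, strings
# kept as strings). Numbers and the literals true/false/null arriving
# as barewords are converted to their R values so valid input round
# trips; anything else stays a trimmed string. Never raises.

tolerant_json <- function(s) {
  chars <- stringr::str_split(s, "")[[1]]
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$n <- length(chars)
  st$c <- chars
  tj_value(st)
}

TJ_WS <- c(" ", "\t", "\r", "\n")
TJ_OPEN_QUOTES <- c("\"", "'", "“", "”", "‘", "’")

tj_peek <- function(st) if (st$i > st$n) NA_character_ else st$c[st$i]

tj_skip_ws <- function(st) {
  while (st$i <= st$n && st$c[st$i] %in% TJ_WS) st$i <- st$i + 1L
}

tj_value <- function(st, stops = c(",", "}", "]", "\n")) {
  tj_skip_ws(st)
  ch <- tj_peek(st)
  if (is.na(ch)) {
    return(NULL)
  }
  if (ch == "{") {
    return(tj_object(st))
  }
  if (ch == "[") {
    return(tj_array(st))
  }
  if (ch %in% TJ_OPEN_QUOTES) {
    return(tj_string(st))
  }
  tj_bareword(st, stops)
}

tj_object <- function(st) {
  st$i <- st$i + 1L # past "{"
  out <- list()
  repeat {
    tj_skip_ws(st)
    ch <- tj_peek(st)
    if (is.na(ch) || ch == "}") {
      if (!is.na(ch)) st$i <- st$i + 1L
      break
    }
    if (ch %in% c(",", ";")) {
      st$i <- st$i + 1L
      next
    }
    if (ch == "]") { # stray close inside a truncated object
      st$i <- st$i + 1L
      next
    }
    key <- if (ch %in% TJ_OPEN_QUOTES) {
      tj_string(st)
    } else {
      tj_bareword(st, stops = c(":", ",", "}", "\n"))
    }
    tj_skip_ws(st)
    if (identical(tj_peek(st), ":")) {
      st$i <- st$i + 1L
      val <- tj_value(st)
    } else {
      val <- NA # key with no value; tolerated
    }
    if (is.character(key) && nzchar(key)) {
      out[[key]] <- val
    }
  }
  out
}

tj_array <- function(st) {
  st$i <- st$i + 1L # past "["
  out <- list()
  repeat {
    tj_skip_ws(st)
    ch <- tj_peek(st)
    if (is.na(ch) || ch == "]") {
      if (!is.na(ch)) st$i <- st$i + 1L
      break
    }
    if (ch %in% c(",", ";")) {
      st$i <- st$i + 1L
      next
    }
    v <- tj_value(st, stops = c(",", "]", "}", "\n"))
    if (!is.null(v)) out[[length(out) + 1L]] <- v
  }
  out
}

tj_close_of <- function(open) {
  switch(open,
    "\"" = "\"",
    "'" = "'",
    "“" = c("”", "“", "\""),
    "”" = c("”", "\""),
    "‘" = c("’", "'"),
    "’" = c("’", "'"),
    open
  )
}

tj_string <- function(st) {
  open <- st$c[st$i]
  closes <- tj_close_of(open)
  st$i <- st$i + 1L
  buf <- character()
  while (st$i <= st$n) {
    ch <- st$c[st$i]
    if (ch == "\\" && st$i < st$n) {
      nxt <- st$c[st$i + 1L]
      esc <- switch(nxt,
        "n" = "\n", "t" = "\t", "r" = "\r", "b" = "\b", "f" = "\f",
        "u" = NA_character_, nxt
      )
      if (is.na(esc)) { # \uXXXX
        if (st$i + 5L <= st$n) {
          hex <- paste(st$c[(st$i + 2L):(st$i + 5L)], collapse = "")
          code <- suppressWarnings(strtoi(hex, 16L))
          esc <- if (is.na(code)) "u" else intToUtf8(code)
          st$i <- st$i + (if (is.na(code)) 0L else 4L)
        } else {
          esc <- "u"
        }
      }
      buf <- c(buf, esc)
      st$i <- st$i + 2L
      next
    }
    if (ch %in% closes) {
      st$i <- st$i + 1L
      return(paste(buf, collapse = ""))
    }
    buf <- c(buf, ch)
    st$i <- st$i + 1L
  }
  paste(buf, collapse = "") # unterminated string: closed at EOF
}

tj_bareword <- function(st, stops) {
  buf <- character()
  while (st$i <= st$n && !(st$c[st$i] %in% stops)) {
    buf <- c(buf, st$c[st$i])
    st$i <- st$i + 1L
  }
  word <- stringr::str_trim(paste(buf, collapse = ""))
  if (word == "true") {
    return(TRUE)
  }
  if (word == "false") {
    return(FALSE)
  }
  if (word == "null") {
    return(NULL)
  }
  if (stringr::str_detect(word, "^-?\\d+(\\.\\d+)?([eE][+-]?\\d+)?$")) {
    return(as.numeric(word))
  }
  word
}
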