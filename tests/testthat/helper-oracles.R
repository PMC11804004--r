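# Independent reference implementations used as oracles. These are
# deliberately written with different algorithms from the package code
# they check.

# --- overlap resolution: explicit cluster-then-argmax ----------------

# connected components of the pairwise span-overlap graph, then argmax
# length with the package's documented tie-break
oracle_resolve_overlaps <- function(m) {
  n <- nrow(m)
  if (n <= 1L) {
    return(dplyr::arrange(m, start, end))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- m$start[i] < m$end[j] && m$start[j] < m$end[i]
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    while (length(frontier) > 0L) {
      comp[frontier] <- cid
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      frontier <- nxt
    }
  }
  keep <- vapply(seq_len(cid), function(k) {
    idx <- which(comp == k)
    len <- m$end[idx] - m$start[idx]
    idx <- idx[len == max(len)]
    idx <- idx[m$start[idx] == min(m$start[idx])]
    prio <- match(m$category[idx], c("DISEASE", "SYMPTOM", "PROCEDURE"))
    idx[which.min(prio)]
  }, integer(1))
  dplyr::arrange(m[sort(keep), ], start, end)
}

random_mention_set <- function(n_max = 20L, doc_len = 120L) {
  n <- sample.int(n_max, 1L)
  start <- sample.int(doc_len - 2L, n, replace = TRUE) - 1L
  len <- sample.int(12L, n, replace = TRUE)
  tibble::tibble(
    doc_id = "d",
    start = as.integer(start),
    end = as.integer(pmin(start + len, doc_len)),
    surface = replicate(n, paste(sample(letters, 4), collapse = "")),
    category = sample(c("DISEASE", "SYMPTOM", "PROCEDURE"), n, replace = TRUE),
    source = "SYNTHETIC"
  )
}

has_overlap <- function(m) {
  if (nrow(m) <= 1L) {
    return(FALSE)
  }
  m <- dplyr::arrange(m, start)
  any(m$end[-nrow(m)] > m$start[-1])
}

# --- strict-grammar parsers ------------------------------------------

# strict reader for the canonical keyed-list serialization
# "{diseases: [a; b], symptoms: [...], medical procedures: [...]}"
oracle_parse_keyed <- function(raw) {
  pat <- paste0(
    "^\\{diseases: \\[(.*?)\\], symptoms: \\[(.*?)\\], ",
    "medical procedures: \\[(.*?)\\]\\}$"
  )
  m <- stringr::str_match(raw, pat)
  stopifnot(!is.na(m[1, 1]))
  split1 <- function(x) {
    if (!nzchar(x)) character() else stringr::str_split(x, "; ")[[1]]
  }
  list(
    DISEASE = split1(m[1, 2]),
    SYMPTOM = split1(m[1, 3]),
    PROCEDURE = split1(m[1, 4])
  )
}

# strict JSON route via jsonlite
oracle_parse_json <- function(raw) {
  obj <- jsonlite::fromJSON(raw, simplifyVector = FALSE)
  ents <- list(DISEASE = character(), SYMPTOM = character(),
               PROCEDURE = character())
  lab <- c(
    "disease" = "DISEASE", "symptom" = "SYMPTOM",
    "medical procedure" = "PROCEDURE"
  )
  for (a in obj$annotations) {
    k <- lab[[tolower(a$category)]]
    ents[[k]] <- c(ents[[k]], a$entity)
  }
  ents
}

# entity vocabulary for generated parser inputs: plain strings that
# survive trimming unchanged
random_entity <- function() {
  n <- sample(1:3, 1L)
  paste(replicate(n, paste(
    sample(letters, sample(3:8, 1L), replace = TRUE), collapse = ""
  )), collapse = " ")
}

random_entity_sets <- function() {
  list(
    DISEASE = unique(replicate(sample(0:4, 1L), random_entity())),
    SYMPTOM = unique(replicate(sample(0:4, 1L), random_entity())),
    PROCEDURE = unique(replicate(sample(0:4, 1L), random_entity()))
  )
}

random_fuzz_string <- function(max_len = 200L) {
  pool <- c(
    letters, LETTERS, 0:9, " ", "\n", "\t", "{", "}", "[", "]", ":",
    ",", ";", "\"", "'", "\\", "-", ".", "(", ")", "“", "”",
    "é", "中", "*", "#", "/"
  )
  n <- sample.int(max_len, 1L)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# --- strict entity-level scorer --------------------------------------

# decodes entities from a label sequence by string run grouping, then
# counts exact (start, end, label) matches; independent of decode_iob
oracle_entity_counts <- function(pred, gold) {
  dec <- function(iob) {
    key <- character()
    i <- 1L
    labs <- iob$label
    while (i <= nrow(iob)) {
      if (startsWith(labs[i], "B")) {
        cat <- sub("^B-?", "", labs[i])
        j <- i
        while (j < nrow(iob) && labs[j + 1L] == sub("^B", "I", labs[i])) {
          j <- j + 1L
        }
        key <- c(key, paste(iob$start[i], iob$end[j], cat, sep = "|"))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    key
  }
  p <- dec(pred)
  g <- dec(gold)
  c(tp = sum(p %in% g), fp = sum(!p %in% g), fn = sum(!g %in% p))
}

# random aligned IOB pair over a shared token sequence
random_iob_pair <- function(n_tok = 40L, categorical = TRUE) {
  toks <- replicate(n_tok, paste(sample(letters, 4), collapse = ""))
  start <- cumsum(c(0L, head(nchar(toks) + 1L, -1L)))
  mk_labels <- function() {
    labs <- rep("O", n_tok)
    i <- 1L
    while (i <= n_tok) {
      if (runif(1) < 0.25) {
        len <- sample(1:3, 1L)
        len <- min(len, n_tok - i + 1L)
        cat <- if (categorical) {
          paste0("-", sample(c("DISEASE", "SYMPTOM", "PROCEDURE"), 1L))
        } else {
          ""
        }
        labs[i] <- paste0("B", cat)
        if (len > 1L) labs[(i + 1L):(i + len - 1L)] <- paste0("I", cat)
        i <- i + len
      } else {
        i <- i + 1L
      }
    }
    labs
  }
  base <- tibble::tibble(
    doc_id = "d", token = toks,
    start = as.integer(start),
    end = as.integer(start + nchar(toks))
  )
  list(
    pred = dplyr::mutate(base, label = mk_labels()),
    gold = dplyr::mutate(base, label = mk_labels())
  )
}

# --- small corpus fixture builders -----------------------------------

write_standoff_fixture <- function(path, rows) {
  lines <- c(
    "filename\tlabel\tstart_span\tend_span\ttext",
    vapply(rows, function(r) paste(r, collapse = "\t"), character(1))
  )
  readr::write_lines(lines, path)
  path
}

fixture_docs_dir <- function(dir, texts) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(texts)) {
    readr::write_file(texts[[id]], file.path(dir, paste0(id, ".txt")))
  }
  dir
}

example_fixture <- function(name) {
  readr::read_file(system.file("extdata", name, package = "clinner"))
}
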