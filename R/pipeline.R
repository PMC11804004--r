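#' Evaluate generations against a merged corpus
#'
#' Runs both evaluation strategies for every `(model_id, variation)`
#' present in `outputs`. Strategy 1 (category-blind) applies to all
#' variations; strategy 2 (categorical, via structured parsing) applies
#' to variations 2 and 3, together with the valid-output ratio. Both
#' entity-level and token-level scoring modes are reported, clearly
#' labeled. A document with no stored generation for a
#' `(model, variation)` pair is scored as an empty generation and
#' counted in the `n_missing` column.
#'
#' @param corpus A `merged_corpus`.
#' @param outputs An outputs tibble (replayed, loaded or simulated).
#' @param split Which documents to score: `"ALL"` (default), `"TEST"`
#'   or `"TRAIN"`.
#' @param modes Scoring modes to report, subset of
#'   `c("ENTITY", "TOKEN")`.
#' @param strategies Which evaluation strategies to run, subset of
#'   `c(1, 2)`; default both.
#' @return A list of class `metrics_report` with tibbles `strategy1`,
#'   `strategy2`, `validity`.
#' @export
evaluate_run <- function(corpus, outputs, split = "ALL",
                         modes = c("ENTITY", "TOKEN"),
                         strategies = c(1L, 2L)) {
  stopifnot(inherits(corpus, "merged_corpus"), all(strategies %in% 1:2))
  modes <- match.arg(modes, several.ok = TRUE)
  ids <- if (split == "ALL") {
    corpus$split$doc_id
  } else {
    corpus$split$doc_id[corpus$split$split == split]
  }
  docs <- filter(corpus$documents, .data$doc_id %in% ids)
  if (nrow(docs) == 0L) {
    abort(paste0("no documents in split ", split))
  }
  # per-document gold, computed once
  gold <- lapply(seq_len(nrow(docs)), function(d) {
    doc <- docs[d, ]
    m <- filter(corpus$mentions, .data$doc_id == doc$doc_id)
    list(
      doc = doc, mentions = m,
      iob_bin = to_iob(doc, m, categorical = FALSE),
      iob_cat = to_iob(doc, m, categorical = TRUE)
    )
  })
  groups <- distinct(outputs, .data$model_id, .data$variation) %>%
    arrange(.data$model_id, .data$variation)
  s1_rows <- list()
  s2_rows <- list()
  val_rows <- list()
  for (g in seq_len(nrow(groups))) {
    mid <- groups$model_id[g]
    v <- groups$variation[g]
    sub <- filter(outputs, .data$model_id == mid, .data$variation == v)
    n_missing <- 0L
    c1 <- list()
    c2 <- list()
    parsed_sets <- list()
    for (gd in gold) {
      row <- filter(sub, .data$doc_id == gd$doc$doc_id)
      if (nrow(row) == 0L) {
        n_missing <- n_missing + 1L
        raw <- ""
      } else {
        raw <- row$raw[[1]]
      }
      if (1L %in% strategies) {
        pred1 <- strategy1_tag(gd$doc, gd$mentions, raw)
        for (mode in modes) {
          c1[[length(c1) + 1L]] <-
            score_iob(pred1, gd$iob_bin, mode) %>% mutate(mode = mode)
        }
      }
      if (v >= 2L && 2L %in% strategies) {
        parsed <- parse_output(raw, v, gd$doc$doc_id)
        parsed_sets[[length(parsed_sets) + 1L]] <- parsed
        pred2 <- strategy2_tag(gd$doc, parsed)
        for (mode in modes) {
          c2[[length(c2) + 1L]] <-
            score_iob(pred2, gd$iob_cat, mode) %>% mutate(mode = mode)
        }
      }
    }
    if (n_missing > 0L) {
      inform(paste0(
        n_missing, " document(s) without stored output for ", mid,
        " variation ", v, "; scored as empty generations"
      ))
    }
    if (1L %in% strategies) {
      c1 <- bind_rows(c1)
      for (mode in modes) {
        agg <- aggregate_scores(filter(c1, .data$mode == mode))
        s1_rows[[length(s1_rows) + 1L]] <- agg %>%
          filter(.data$label == "micro avg") %>%
          mutate(model_id = mid, variation = v, mode = mode,
                 n_missing = n_missing)
      }
    }
    if (v >= 2L && 2L %in% strategies) {
      c2 <- bind_rows(c2)
      for (mode in modes) {
        cm <- filter(c2, .data$mode == mode)
        # guarantee a row per category even with zero counts
        pad <- tibble(label = CATEGORIES, tp = 0L, fp = 0L, fn = 0L)
        agg <- aggregate_scores(bind_rows(
          cm %>% select("label", "tp", "fp", "fn"), pad
        ))
        s2_rows[[length(s2_rows) + 1L]] <- agg %>%
          mutate(model_id = mid, variation = v, mode = mode)
      }
      val_rows[[length(val_rows) + 1L]] <- tibble(
        model_id = mid, variation = v,
        ratio = valid_output_ratio(parsed_sets),
        n_docs = length(parsed_sets)
      )
    }
  }
  order_cols <- function(x, extra = "label") {
    if (nrow(x) == 0L) return(x)
    select(x, dplyr::all_of(c(
      "model_id", "variation", extra, "mode",
      "precision", "recall", "f1", "support", "tp", "fp", "fn"
    )), dplyr::any_of("n_missing"))
  }
  s1 <- order_cols(bind_rows(s1_rows)) %>% select(-dplyr::any_of("label"))
  s2 <- order_cols(bind_rows(s2_rows))
  if ("label" %in% names(s2)) s2 <- rename(s2, category = "label")
  out <- list(strategy1 = s1, strategy2 = s2, validity = bind_rows(val_rows))
  if (is.null(out$validity) || nrow(out$validity) == 0L) {
    out$validity <- tibble(
      model_id = character(), variation = integer(),
      ratio = numeric(), n_docs = integer()
    )
  }
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n-- strategy 1 (category-blind) --\n")
  print(x$strategy1)
  if (nrow(x$strategy2) > 0L) {
    cat("-- strategy 2 (categorical) --\n")
    print(x$strategy2)
    cat("-- valid-output ratio --\n")
    print(x$validity)
  }
  invisible(x)
}

#' Write a metrics report as CSV files
#'
#' Writes `strategy1.csv`, `strategy2.csv` and `validity.csv` with fixed
#' column order into `dir`. Re-running on identical inputs reproduces
#' the files byte for byte.
#'
#' @param report A `metrics_report` from [evaluate_run()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s1 <- report$strategy1 %>%
    select(dplyr::all_of(c("model_id", "variation", "mode", "precision",
                           "recall", "f1", "support")))
  s2 <- report$strategy2 %>%
    select(dplyr::all_of(c("model_id", "variation", "category", "mode",
                           "precision", "recall", "f1", "support")))
  readr::write_csv(s1, file.path(dir, "strategy1.csv"))
  readr::write_csv(s2, file.path(dir, "strategy2.csv"))
  readr::write_csv(report$validity, file.path(dir, "validity.csv"))
  invisible(dir)
}

#' Save / load a merged corpus as plain-text artifacts
#'
#' Documents as one `.txt` file each under `documents/`, mentions as
#' JSONL, split as CSV, plus categorical and binary gold CoNLL files.
#'
#' @param corpus A `merged_corpus`.
#' @param dir Directory.
#' @return `dir` / the reloaded `merged_corpus`.
#' @export
save_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "merged_corpus"))
  docdir <- file.path(dir, "documents")
  dir.create(docdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    readr::write_file(
      corpus$documents$text[i],
      file.path(docdir, paste0(corpus$documents$doc_id[i], ".txt"))
    )
  }
  write_mentions_jsonl(corpus$mentions, file.path(dir, "mentions.jsonl"))
  readr::write_csv(corpus$split, file.path(dir, "split.csv"))
  iobs <- lapply(seq_len(nrow(corpus$documents)), function(i) {
    doc <- corpus$documents[i, ]
    m <- filter(corpus$mentions, .data$doc_id == doc$doc_id)
    list(cat = to_iob(doc, m, TRUE), bin = to_iob(doc, m, FALSE))
  })
  write_conll(bind_rows(lapply(iobs, `[[`, "cat")),
              file.path(dir, "gold_iob.conll"))
  write_conll(bind_rows(lapply(iobs, `[[`, "bin")),
              file.path(dir, "gold_iob_binary.conll"))
  invisible(dir)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(dir) {
  documents <- read_documents(file.path(dir, "documents"))
  mentions <- read_mentions_jsonl(file.path(dir, "mentions.jsonl"))
  split <- readr::read_csv(file.path(dir, "split.csv"),
                           show_col_types = FALSE)
  corpus <- list(
    documents = documents, mentions = mentions,
    split = as_tibble(split)
  )
  class(corpus) <- "merged_corpus"
  corpus
}

#' Read a run configuration file
#'
#' YAML configuration shared by the `cmd_*` stage commands; see the
#' package vignette for the schema.
#'
#' @param path Path to a YAML file.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  yaml::read_yaml(path)
}

cfg <- function(config, ..., default = NULL) {
  for (k in c(...)) {
    if (is.null(config)) {
      return(default)
    }
    config <- config[[k]]
  }
  config %||% default
}

#' Stage command: generate a synthetic corpus and simulated outputs
#'
#' Writes the same document/TSV/JSONL artifact formats as the real
#' corpus path, so the downstream stages run unmodified on synthetic
#' data: per-category standoff TSVs, a documents directory, a test-id
#' list, and one outputs JSONL per model profile.
#'
#' @param config A configuration list or path to a YAML file. Keys
#'   used: `out_dir`, `simulate$spec`, `simulate$params` (one set of
#'   simulator parameters, or a named list of them, one per simulated
#'   model profile), `prompt$variations`.
#' @return Invisibly, a list with the generated `corpus`, `bookkeeping`
#'   and output file paths.
#' @export
cmd_simulate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- cfg(config, "out_dir", default = ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(synthetic_spec, cfg(config, "simulate", "spec",
                                      default = list()))
  gen <- generate_corpus(spec)
  corpus <- gen$corpus
  # standoff artifacts
  docdir <- file.path(out_dir, "documents")
  dir.create(docdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    readr::write_file(
      corpus$documents$text[i],
      file.path(docdir, paste0(corpus$documents$doc_id[i], ".txt"))
    )
  }
  header <- "filename\tlabel\tstart_span\tend_span\ttext"
  for (k in CATEGORIES) {
    m <- filter(corpus$mentions, .data$category == k)
    lines <- c(header, sprintf(
      "%s\t%s\t%d\t%d\t%s", m$doc_id, k, m$start, m$end, m$surface
    ))
    readr::write_lines(
      lines,
      file.path(out_dir, paste0("annotations_", tolower(k), ".tsv"))
    )
  }
  test_ids <- corpus$split$doc_id[corpus$split$split == "TEST"]
  readr::write_lines(test_ids, file.path(out_dir, "test_ids.txt"))
  # simulated generations
  params_cfg <- cfg(config, "simulate", "params", default = list())
  if (length(params_cfg) > 0L && !is.null(params_cfg[[1]]) &&
      is.list(params_cfg[[1]])) {
    profiles <- params_cfg
  } else {
    profiles <- list(simulated = params_cfg)
  }
  variations <- as.integer(cfg(config, "prompt", "variations",
                               default = 1:3))
  out_paths <- character()
  for (mid in names(profiles)) {
    params <- do.call(simulator_params, profiles[[mid]])
    outs <- simulate_outputs(corpus, params, variations, model_id = mid)
    p <- file.path(out_dir, paste0("outputs_", mid, ".jsonl"))
    save_outputs(outs, p)
    out_paths <- c(out_paths, p)
  }
  invisible(list(
    corpus = corpus, bookkeeping = gen$bookkeeping, outputs = out_paths
  ))
}

#' Stage command: merge standoff releases into the unified corpus
#'
#' Reads the documents directory and the per-category standoff TSVs,
#' builds the overlap-free multiclass corpus with its train/test split,
#' and writes corpus artifacts (mentions JSONL, split CSV, gold CoNLL
#' files) plus summary statistics CSVs.
#'
#' @param config A configuration list or path to a YAML file. Keys
#'   used: `paths$documents`, `paths$annotations` (named list
#'   `category -> list(path, source)`), `paths$test_ids`,
#'   `paths$corpus_dir`.
#' @return Invisibly, the `merged_corpus`.
#' @export
cmd_merge <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  documents <- read_documents(cfg(config, "paths", "documents"))
  ann <- cfg(config, "paths", "annotations", default = list())
  if (length(ann) == 0L) {
    abort("config paths$annotations is empty")
  }
  mentions <- lapply(names(ann), function(k) {
    read_standoff_tsv(
      ann[[k]]$path, category = toupper(k),
      source = toupper(ann[[k]]$source %||% "SYNTHETIC")
    )
  })
  test_path <- cfg(config, "paths", "test_ids")
  test_ids <- if (is.null(test_path)) {
    character()
  } else {
    readr::read_lines(test_path)
  }
  test_ids <- test_ids[nzchar(test_ids)]
  corpus <- build_merged_corpus(documents, mentions, test_ids)
  corpus_dir <- cfg(config, "paths", "corpus_dir",
                    default = file.path(cfg(config, "out_dir",
                                            default = "."), "corpus"))
  save_corpus(corpus, corpus_dir)
  stats <- corpus_stats(corpus)
  readr::write_csv(stats$mention_counts,
                   file.path(corpus_dir, "stats_mentions.csv"))
  readr::write_csv(
    mutate(stats$doc_counts, mean_doc_words = stats$mean_doc_words),
    file.path(corpus_dir, "stats_documents.csv")
  )
  invisible(corpus)
}

#' Stage command: evaluate stored generations
#'
#' Loads the merged-corpus artifacts and one or more outputs JSONL
#' files, runs both evaluation strategies, and writes the report CSVs.
#'
#' @param config A configuration list or path to a YAML file. Keys
#'   used: `paths$corpus_dir`, `paths$outputs` (path or vector of
#'   paths), `paths$report_dir`, `scoring$split`.
#' @return Invisibly, the `metrics_report`.
#' @export
cmd_evaluate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  corpus <- load_corpus(cfg(config, "paths", "corpus_dir"))
  out_paths <- unlist(cfg(config, "paths", "outputs"))
  if (is.null(out_paths) || length(out_paths) == 0L) {
    abort("config paths$outputs is empty")
  }
  outputs <- bind_rows(lapply(out_paths, load_outputs))
  report <- evaluate_run(
    corpus, outputs,
    split = cfg(config, "scoring", "split", default = "ALL")
  )
  report_dir <- cfg(config, "paths", "report_dir",
                    default = file.path(cfg(config, "out_dir",
                                            default = "."), "report"))
  write_report(report, report_dir)
  invisible(report)
}
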