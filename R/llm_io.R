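# Backend registry: model_id -> function(prompt, doc_id, variation)
# returning either a raw string or list(raw = , meta = ).
.backends <- new.env(parent = emptyenv())

#' Register a generation backend
#'
#' A backend is any function `function(prompt, doc_id, variation)`
#' returning the raw generation as a string (or a list with elements
#' `raw` and `meta`). Real-model adapters, replay stores and the
#' simulator all plug in through this one contract, so evaluation code
#' never needs model weights.
#'
#' @param model_id Model identifier the backend answers for.
#' @param backend The backend function.
#' @return `model_id`, invisibly.
#' @export
llm_register_backend <- function(model_id, backend) {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.function(backend))
  assign(model_id, backend, envir = .backends)
  invisible(model_id)
}

#' Remove registered backends
#' @param model_id Optional id to remove; default removes all.
#' @return Invisibly, the removed ids.
#' @export
llm_clear_backends <- function(model_id = NULL) {
  ids <- if (is.null(model_id)) ls(.backends) else model_id
  rm(list = intersect(ids, ls(.backends)), envir = .backends)
  invisible(ids)
}

#' Query a backend for one generation
#'
#' Returns the backend's generation verbatim; refusals and empty
#' generations are ordinary records and never raise. A backend error is
#' recorded in `meta$error` with an empty `raw`.
#'
#' @param model_id Registered model identifier.
#' @param prompt The rendered prompt string.
#' @param doc_id Document id the prompt was rendered for.
#' @param variation Prompt variation in `1:3`.
#' @return A one-row outputs tibble (`doc_id`, `model_id`, `variation`,
#'   `raw`, `meta` list-column).
#' @export
llm_generate <- function(model_id, prompt, doc_id, variation) {
  if (!exists(model_id, envir = .backends, inherits = FALSE)) {
    abort(paste0("no backend registered for model: ", model_id))
  }
  backend <- get(model_id, envir = .backends)
  res <- tryCatch(
    backend(prompt, doc_id, variation),
    error = function(e) list(raw = "", meta = list(error = conditionMessage(e)))
  )
  if (is.character(res)) res <- list(raw = res, meta = list())
  if (is.null(res$raw)) res$raw <- ""
  tibble(
    doc_id = doc_id, model_id = model_id,
    variation = as.integer(variation),
    raw = as.character(res$raw),
    meta = list(res$meta %||% list())
  )
}

#' Replay backend over stored outputs
#'
#' Looks generations up by `(doc_id, variation)` in a stored outputs
#' tibble; a missing key yields an empty generation with
#' `meta$missing = TRUE`, so replayed evaluation runs are fully
#' deterministic.
#'
#' @param outputs Outputs tibble (e.g. from [load_outputs()]).
#' @return A backend function for [llm_register_backend()].
#' @export
llm_backend_replay <- function(outputs) {
  force(outputs)
  function(prompt, doc_id, variation) {
    hit <- outputs[outputs$doc_id == doc_id &
                     outputs$variation == variation, ]
    if (nrow(hit) == 0L) {
      return(list(raw = "", meta = list(missing = TRUE)))
    }
    list(raw = hit$raw[[1]], meta = hit$meta[[1]])
  }
}

#' Save / load generation records as JSONL
#'
#' One object per line with keys `doc_id`, `model_id`, `variation`,
#' `raw`, `meta`. The round trip is lossless; malformed lines are
#' skipped on load with a warning that reports their count.
#'
#' @param outputs Outputs tibble.
#' @param path File path.
#' @return For `save_outputs`, `path` invisibly; for `load_outputs`, an
#'   outputs tibble with attribute `skipped`.
#' @export
save_outputs <- function(outputs, path) {
  lines <- vapply(seq_len(nrow(outputs)), function(i) {
    jsonlite::toJSON(
      list(
        doc_id = outputs$doc_id[i], model_id = outputs$model_id[i],
        variation = outputs$variation[i], raw = outputs$raw[i],
        meta = outputs$meta[[i]]
      ),
      auto_unbox = TRUE, null = "null"
    )
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname save_outputs
#' @export
load_outputs <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  skipped <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) NULL
    )
    if (is.null(obj) || is.null(obj$doc_id) || is.null(obj$model_id) ||
        is.null(obj$variation)) {
      skipped <- skipped + 1L
      next
    }
    recs[[i]] <- tibble(
      doc_id = obj$doc_id, model_id = obj$model_id,
      variation = as.integer(obj$variation),
      raw = as.character(obj$raw %||% ""),
      meta = list(obj$meta %||% list())
    )
  }
  if (skipped > 0L) {
    warn(paste0(skipped, " malformed JSONL line(s) skipped in ", path))
  }
  out <- bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble(
      doc_id = character(), model_id = character(),
      variation = integer(), raw = character(), meta = list()
    )
  }
  attr(out, "skipped") <- skipped
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
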