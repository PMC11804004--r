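#' Score a predicted IOB sequence against gold
#'
#' Both sequences must cover the identical token sequence (a mismatch is
#' a pipeline bug and is fatal). In `ENTITY` mode, label runs are
#' decoded into mention spans and compared by exact span-plus-label
#' equality (strict entity-level matching). In `TOKEN` mode, non-`O`
#' token labels are compared positionally by their category part; a
#' category mismatch counts as both a false positive (under the
#' predicted label) and a false negative (under the gold label).
#'
#' @param pred,gold IOB tibbles over the same document.
#' @param mode `"ENTITY"` (default) or `"TOKEN"`.
#' @return A tibble of per-label counts (`label`, `tp`, `fp`, `fn`);
#'   binary sequences report under label `"ENTITY"`.
#' @export
score_iob <- function(pred, gold, mode = c("ENTITY", "TOKEN")) {
  mode <- match.arg(mode)
  if (nrow(pred) != nrow(gold) ||
      !identical(pred$start, gold$start) ||
      !identical(pred$end, gold$end)) {
    abort("pred and gold do not cover the same token sequence")
  }
  if (mode == "ENTITY") {
    pe <- decode_iob(pred) %>%
      mutate(label = dplyr::coalesce(.data$category, "ENTITY"))
    ge <- decode_iob(gold) %>%
      mutate(label = dplyr::coalesce(.data$category, "ENTITY"))
    pk <- paste(pe$start, pe$end, pe$label)
    gk <- paste(ge$start, ge$end, ge$label)
    counts <- bind_rows(
      tibble(label = pe$label, tp = as.integer(pk %in% gk),
             fp = as.integer(!pk %in% gk), fn = 0L),
      tibble(label = ge$label, tp = 0L, fp = 0L,
             fn = as.integer(!gk %in% pk))
    )
  } else {
    lab <- function(x) {
      ifelse(x == "O", "O",
             ifelse(stringr::str_detect(x, "-"),
                    stringr::str_remove(x, "^[BI]-"), "ENTITY"))
    }
    pl <- lab(pred$label)
    gl <- lab(gold$label)
    counts <- bind_rows(
      tibble(label = pl[pl != "O"],
             tp = as.integer((gl == pl)[pl != "O"]),
             fp = as.integer((gl != pl)[pl != "O"]), fn = 0L),
      tibble(label = gl[gl != "O"], tp = 0L, fp = 0L,
             fn = as.integer((pl != gl)[gl != "O"]))
    )
  }
  out <- counts %>%
    group_by(.data$label) %>%
    summarise(across(c("tp", "fp", "fn"), sum), .groups = "drop")
  if (nrow(out) == 0L) {
    out <- tibble(label = character(), tp = integer(), fp = integer(),
                  fn = integer())
  }
  out
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Aggregate per-document counts into a metrics table
#'
#' Counts are pooled (micro-averaged) over documents per label, and a
#' `micro avg` row pools across labels as well. Zero support yields zero
#' scores; support columns make the denominators auditable.
#'
#' @param counts Row-bound per-label count tibbles from [score_iob()].
#' @return A tibble with columns `label`, `precision`, `recall`, `f1`,
#'   `tp`, `fp`, `fn`, `support` (gold mention count).
#' @export
aggregate_scores <- function(counts) {
  if (nrow(counts) == 0L) {
    counts <- tibble(label = character(), tp = integer(), fp = integer(),
                     fn = integer())
  }
  per <- counts %>%
    group_by(.data$label) %>%
    summarise(across(c("tp", "fp", "fn"), sum), .groups = "drop")
  micro <- per %>%
    summarise(across(c("tp", "fp", "fn"), sum)) %>%
    mutate(label = "micro avg")
  all_rows <- bind_rows(per, micro)
  scores <- t(mapply(prf, all_rows$tp, all_rows$fp, all_rows$fn))
  bind_cols(
    all_rows["label"],
    as_tibble(scores),
    all_rows[c("tp", "fp", "fn")]
  ) %>%
    mutate(support = .data$tp + .data$fn)
}

#' Valid-output ratio
#'
#' Fraction of documents whose generation parsed into at least one
#' canonical entity in the requested structure.
#'
#' @param parsed_sets List of `parsed_entities`, one per document.
#' @return A number in `[0, 1]`.
#' @export
valid_output_ratio <- function(parsed_sets) {
  if (length(parsed_sets) == 0L) {
    abort("valid_output_ratio requires at least one parsed set")
  }
  mean(vapply(parsed_sets, parsed_ok, logical(1)))
}
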