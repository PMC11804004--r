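PLACEHOLDER <- "{{CLINICAL_TEXT}}"

# The three prompt variations, of increasing structural strictness:
# 1 free-form, 2 keyed Python-dictionary-like list, 3 JSON annotations.
# The clinical note is substituted for the placeholder sentinel.
PROMPT_TEMPLATES <- c(
  `1` = paste0(
    "You are an expert in labeling clinical notes with mentions of ",
    "diseases, symptoms, and medical procedures. Extract the mentions ",
    "of diseases, symptoms, and medical procedures from the following ",
    "clinical note: ", PLACEHOLDER
  ),
  `2` = paste0(
    "You are an expert in labeling clinical notes with mentions of ",
    "diseases, symptoms, and medical procedures. Please identify the ",
    "entities of types [disease, symptom, medical procedure] in the ",
    "following clinical document. The output must be formatted like ",
    "this: {diseases: [list of diseases], symptoms: [list of symptoms], ",
    "medical procedures: [list of medical procedures]} Document: ",
    PLACEHOLDER
  ),
  `3` = paste0(
    "You are an expert in labeling clinical notes with mentions of ",
    "diseases, symptoms, and medical procedures. Analyze the following ",
    "clinical note and identify all mentions of diseases, symptoms, ",
    "and medical procedures. Provide the annotations in a structured ",
    "JSON format. Each identified entity should be categorized as ",
    "either a disease, symptom, or medical procedure. Example JSON ",
    "format for annotations (Note: Replace \"entity1\", \"entity2\", ",
    "etc., with actual entity names: { \"annotations\": [ { \"entity\": ",
    "\"entity1\", \"category\": \"disease\" }, { \"entity\": ",
    "\"entity2\", \"category\": \"symptom\" }, { \"entity\": ",
    "\"entity3\", \"category\": \"medical procedure\" } ... more ",
    "entities ] }. Now, analyze this clinical note: ", PLACEHOLDER
  )
)

#' The three prompt templates
#'
#' Returns the zero-shot prompt variations used to query the models.
#' Variation 1 requests no output format, variation 2 a simple keyed
#' list (a Python-dictionary-like structure), variation 3 a structured
#' JSON `annotations` array. Each template contains the placeholder
#' sentinel `{{CLINICAL_TEXT}}` exactly once.
#'
#' @return A tibble with columns `variation` (integer) and `template`.
#' @export
#' @examples
#' prompt_templates()$variation
prompt_templates <- function() {
  tibble(
    variation = as.integer(names(PROMPT_TEMPLATES)),
    template = unname(PROMPT_TEMPLATES)
  )
}

#' The placeholder sentinel used in prompt templates
#' @return A single string.
#' @export
prompt_placeholder <- function() PLACEHOLDER

#' Render a prompt for a document
#'
#' Substitutes the clinical note text for the placeholder; all other
#' template bytes are left unchanged. Rendering is pure and
#' deterministic.
#'
#' @param variation Integer in `1:3`.
#' @param doc A one-row document tibble or list with `doc_id`, `text`.
#' @return The rendered prompt string.
#' @export
render_prompt <- function(variation, doc) {
  if (!length(variation) == 1L || !variation %in% 1:3) {
    abort("variation must be 1, 2 or 3")
  }
  doc <- as_doc(doc)
  stopifnot(nzchar(doc$text))
  # sub(fixed = TRUE) substitutes both pattern and replacement literally
  sub(PLACEHOLDER, doc$text, PROMPT_TEMPLATES[[as.character(variation)]],
      fixed = TRUE)
}

#' Export the prompt templates as YAML
#'
#' Writes the templates under keys `prompt.variation.<k>` so non-default
#' prompts can be configured externally.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_prompt_templates <- function(path) {
  obj <- list(prompt = list(variation = as.list(stats::setNames(
    unname(PROMPT_TEMPLATES), names(PROMPT_TEMPLATES)
  ))))
  yaml::write_yaml(obj, path)
  invisible(path)
}
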