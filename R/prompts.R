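# Prompt and sequence builders for LLM-based classification routes.
#
# Network calls are never made here: prompts are deterministic strings, and
# completions come through an abstract provider (a function prompt ->
# completion text) so tests use canned responses.

#' Build an in-context-learning classification prompt
#'
#' Assembles, in order: the task description, the checklist item
#' descriptions, the shot examples (omitted for zero-shot), and the entire
#' article text. Deterministic for fixed inputs.
#'
#' @param article A single-article `consort_corpus` slice.
#' @param items A `consort_checklist` data frame of the items to ask about.
#' @param shots 0, 1 or 5 example demonstrations.
#' @param shot_pool Data frame with columns `text` and `labels` providing
#'   the demonstration pool (required when `shots > 0`; the first `shots`
#'   rows are used).
#' @return The prompt string.
#' @export
build_icl_prompt <- function(article, items, shots = 0L, shot_pool = NULL) {
  if (!shots %in% c(0L, 1L, 5L)) stopf("shots must be 0, 1 or 5")
  if (shots > 0L) {
    if (is.null(shot_pool) || nrow(shot_pool) < shots) {
      stopf("shot pool has %d examples but %d are required",
            if (is.null(shot_pool)) 0L else nrow(shot_pool), shots)
    }
  }
  task <- paste0(
    "You are assisting with checking the reporting completeness of a ",
    "randomized controlled trial publication against the CONSORT checklist. ",
    "For each sentence of the article below, list the checklist item codes ",
    "the sentence reports, or 'none' if it reports no item.")
  item_block <- paste(sprintf("%s (%s): %s", items$code, items$title,
                              items$description), collapse = "\n")
  parts <- c(task, "Checklist items:", item_block)
  if (shots > 0L) {
    ex <- shot_pool[seq_len(shots), , drop = FALSE]
    ex_block <- paste(sprintf("Sentence: %s\nLabels: %s", ex$text,
                              ifelse(nzchar(ex$labels), gsub("|", ", ",
                                     ex$labels, fixed = TRUE), "none")),
                      collapse = "\n\n")
    parts <- c(parts, "Examples:", ex_block)
  }
  ordered <- article[order(article$sentence_index), , drop = FALSE]
  parts <- c(parts, "Article:", paste(ordered$text, collapse = "\n"))
  paste(parts, collapse = "\n\n")
}

#' Format a sentence as a generative classification sequence
#'
#' Builds the text-generation training sequence
#' `"[SENTENCE]. This sentence describes [LABEL]"` used when the task is
#' cast as sequence completion by a generative language model. The sentence
#' part is expected to carry its section-header prefix already.
#'
#' @param sentence_with_headers Header-prefixed sentence text.
#' @param label Item code.
#' @return The formatted sequence.
#' @seealso [parse_generative_sequence()]
#' @export
format_generative_sequence <- function(sentence_with_headers, label) {
  if (!is_string(label) || !nzchar(trim(label))) {
    stopf("label must be a non-empty item code")
  }
  sprintf("%s. This sentence describes %s", sentence_with_headers, label)
}

#' Recover the label from a generative sequence
#'
#' Inverse of [format_generative_sequence()] by suffix parse.
#'
#' @param sequence A formatted sequence.
#' @return List with `sentence` and `label`, or `NULL` if the sequence does
#'   not match the template.
#' @export
parse_generative_sequence <- function(sequence) {
  m <- regmatches(sequence,
                  regexec("^(.*)\\. This sentence describes (\\S+)$", sequence))[[1]]
  if (length(m) != 3L) return(NULL)
  list(sentence = m[2], label = m[3])
}
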