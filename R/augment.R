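# Data augmentation for rare checklist items.
#
# Two families: easy data augmentation (EDA: synonym replacement, random
# insertion, random swap, random deletion, at perturbation rate alpha) with
# a pluggable synonym provider (general-English lexicon or a table-driven
# adapter, e.g. for a UMLS-style clinical synonym table), and LLM
# prompt-based augmentation (rephrasing existing instances, or generating
# new sentences from edited item descriptions), with deterministic prompt
# builders and a response parser. Only single-label instances of the eight
# rare items are augmentation candidates, and each augmented instance is a
# (preceding, target, trailing) triple carrying exactly one label.

EDA_STOPWORDS <- c(
  "a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "in",
  "is", "it", "its", "of", "on", "or", "that", "the", "this", "to", "was",
  "were", "with")

#' Table-driven synonym provider
#'
#' Wraps a named list (word -> character vector of synonyms) as a synonym
#' provider. Used both for clinical (UMLS-style) synonym tables and for
#' test lexicons. Lookups are case-insensitive and deterministic, and a
#' word is never returned as its own synonym.
#'
#' @param table Named list mapping words to synonym vectors.
#' @return A function `word -> character vector` (possibly empty).
#' @export
synonym_provider_table <- function(table) {
  names(table) <- tolower(names(table))
  function(word) {
    w <- tolower(word)
    syn <- table[[w]] %||% character(0)
    setdiff(syn, w)
  }
}

# Small built-in general-English lexicon (common trial-report vocabulary);
# a stand-in default so EDA runs out of the box. Users supply richer
# providers (WordNet, UMLS) through the same contract.
.default_lexicon <- list(
  big = c("large", "great"), large = c("big", "sizeable"),
  small = c("little", "minor"), show = c("demonstrate", "indicate"),
  showed = c("demonstrated", "indicated"), use = c("employ", "apply"),
  used = c("employed", "applied"), study = c("trial", "investigation"),
  trial = c("study", "experiment"), result = c("outcome", "finding"),
  results = c("outcomes", "findings"), method = c("approach", "procedure"),
  methods = c("approaches", "procedures"), begin = c("start", "commence"),
  began = c("started", "commenced"), change = c("alter", "modify"),
  changed = c("altered", "modified"), important = c("significant", "notable"),
  measure = c("assess", "evaluate"), measured = c("assessed", "evaluated"),
  patients = c("participants", "subjects"),
  participants = c("patients", "subjects"),
  received = c("got", "obtained"), stopped = c("halted", "ended"),
  assigned = c("allocated", "randomized"), groups = c("arms", "cohorts"))

#' Built-in general-English synonym provider
#'
#' @return A synonym provider over a small built-in lexicon of common
#'   trial-report vocabulary.
#' @export
synonym_provider_lexicon <- function() synonym_provider_table(.default_lexicon)

#' Select augmentation candidate sentences
#'
#' Returns the sentences eligible for augmentation: those carrying exactly
#' one label, where that label is one of the rare items (fewer than 100
#' instances corpus-wide).
#'
#' @param corpus A labelled `consort_corpus`.
#' @param rare Character vector of rare item codes; defaults to
#'   [rare_items()].
#' @return The eligible `consort_corpus` rows.
#' @export
select_candidates <- function(corpus, rare = rare_items()) {
  labs <- split_labels(corpus$labels)
  keep <- lengths(labs) == 1L &
    vapply(labs, function(l) length(l) == 1L && l %in% rare, logical(1))
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_corpus(out)
}

words_of <- function(sentence) {
  w <- strsplit(trim(sentence), "\\s+")[[1]]
  w[nzchar(w)]
}

#' Apply one EDA perturbation to a sentence
#'
#' The four classic operations at perturbation rate `rate`:
#' `random_deletion` removes each word independently with probability
#' `rate` (always retaining at least one word); `random_swap` exchanges
#' `ceiling(rate * L)` random position pairs; `random_insertion` inserts a
#' synonym of a random word at a random position, `ceiling(rate * L)`
#' times; `synonym_replacement` replaces `ceiling(rate * L)` eligible
#' (non-stop-word, synonym-bearing) words with a random synonym.
#' Deterministic for a fixed RNG state.
#'
#' @param sentence Sentence string.
#' @param op_kind One of `"synonym_replacement"`, `"random_insertion"`,
#'   `"random_swap"`, `"random_deletion"`.
#' @param rate Perturbation rate in `[0, 1]`; `rate = 0` is the identity.
#' @param synonyms A synonym provider (see [synonym_provider_table()]).
#' @return The perturbed sentence.
#' @export
eda_transform <- function(sentence,
                          op_kind = c("synonym_replacement", "random_insertion",
                                      "random_swap", "random_deletion"),
                          rate = 0.1,
                          synonyms = synonym_provider_lexicon()) {
  op_kind <- match.arg(op_kind)
  if (rate < 0 || rate > 1) stopf("rate must be in [0, 1]")
  w <- words_of(sentence)
  L <- length(w)
  if (L == 0L || rate == 0) return(sentence)
  n_ops <- ceiling(rate * L)
  w <- switch(op_kind,
    random_deletion = {
      keep <- runif(L) >= rate
      if (!any(keep)) keep[sample.int(L, 1L)] <- TRUE
      w[keep]
    },
    random_swap = {
      if (L >= 2L) {
        for (k in seq_len(n_ops)) {
          ij <- sample.int(L, 2L)
          w[ij] <- w[rev(ij)]
        }
      }
      w
    },
    random_insertion = {
      for (k in seq_len(n_ops)) {
        cand <- sample.int(length(w), length(w))
        syn <- character(0)
        for (i in cand) {
          syn <- synonyms(gsub("[[:punct:]]+$", "", w[i]))
          if (length(syn)) break
        }
        if (length(syn)) {
          ins <- syn[sample.int(length(syn), 1L)]
          at <- sample.int(length(w) + 1L, 1L)
          w <- append(w, ins, after = at - 1L)
        }
      }
      w
    },
    synonym_replacement = {
      bare <- gsub("[[:punct:]]+$", "", tolower(w))
      eligible <- which(!(bare %in% EDA_STOPWORDS) &
                        vapply(bare, function(x) length(synonyms(x)) > 0,
                               logical(1)))
      if (length(eligible)) {
        pick <- eligible[sample.int(length(eligible),
                                    min(n_ops, length(eligible)))]
        for (i in pick) {
          syn <- synonyms(bare[i])
          w[i] <- syn[sample.int(length(syn), 1L)]
        }
      }
      w
    })
  paste(w, collapse = " ")
}

#' Generate EDA variations of one candidate sentence
#'
#' Produces `n_aug` augmentation instances (default 6) for a single-label
#' candidate sentence, each via one randomly chosen EDA operation at rate
#' `alpha`. The instance keeps the original's label, its real neighbouring
#' sentences as preceding/trailing context, and its section path.
#'
#' @param record One row of a `consort_corpus` (the candidate sentence).
#' @param corpus The corpus the record came from (for its neighbours).
#' @param n_aug Number of variations (default 6).
#' @param alpha Perturbation rate (default 0.1).
#' @param synonyms Synonym provider; providers backed by a clinical synonym
#'   table give the UMLS-flavoured EDA variant.
#' @param method Method tag stored on the instances (`"eda"` or
#'   `"synonym_eda"`).
#' @param seed Optional seed for reproducible output.
#' @return Data frame of class `consort_augmentation`: `method`,
#'   `source_article_id`, `source_id`, `preceding`, `target`, `trailing`,
#'   `label`, `section_path`.
#' @export
eda_augment <- function(record, corpus, n_aug = 6L, alpha = 0.1,
                        synonyms = synonym_provider_lexicon(),
                        method = "eda", seed = NULL) {
  labs <- split_labels(record$labels)[[1]]
  if (length(labs) != 1L) {
    stopf("eda_augment expects a single-label candidate (got %d labels)",
          length(labs))
  }
  art <- corpus[corpus$article_id == record$article_id, , drop = FALSE]
  w <- build_context_window(art, record$sentence_index)
  ops <- c("synonym_replacement", "random_insertion", "random_swap",
           "random_deletion")
  gen <- function() {
    out <- vector("list", n_aug)
    for (k in seq_len(n_aug)) {
      op <- ops[sample.int(length(ops), 1L)]
      out[[k]] <- data.frame(
        method = method,
        source_article_id = record$article_id,
        source_id = sprintf("%s:%d", record$article_id, record$sentence_index),
        preceding = w$preceding,
        target = eda_transform(w$target, op, alpha, synonyms),
        trailing = w$trailing,
        label = labs,
        section_path = record$section_path,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  res <- if (is.null(seed)) gen() else with_seed(seed, gen())
  class(res) <- c("consort_augmentation", "data.frame")
  res
}

#' Build the rephrasing augmentation prompt
#'
#' The fixed rephrasing template with the sentence and the requested number
#' of rephrasings substituted.
#'
#' @param sentence The positively labelled sentence to rephrase.
#' @param n Number of rephrasings (default 6).
#' @return The prompt string.
#' @export
build_rephrase_prompt <- function(sentence, n = 6L) {
  if (!is_string(sentence) || !nzchar(trim(sentence))) {
    stopf("sentence must be non-empty")
  }
  if (n < 1L) stopf("n must be >= 1")
  paste0(
    "You are a scientific researcher writing a research paper for ",
    "randomized clinical trials. Please rephrase the following sentence ",
    n, " times: ", sentence, ". For the ", n, " rephrased sentences, also ",
    "provide an example preceding sentence and an example trailing ",
    "sentence. Vary the sentence structure and sentence complexity for ",
    "each sentence. Also, vary the use of introductory prepositional ",
    "phrases in all sentences")
}

#' Build the generative augmentation prompt
#'
#' The fixed generative template, asking for `n` one-sentence examples of
#' the (edited) checklist item description.
#'
#' @param item One checklist item row (or an item code).
#' @param n Number of examples (6 or 8 in typical use).
#' @param description Optional pre-edited description; defaults to
#'   [edit_item_description()] of the item's description.
#' @return The prompt string.
#' @export
build_generative_prompt <- function(item, n = 8L, description = NULL) {
  if (is.character(item)) {
    items <- consort_checklist()
    row <- items[items$code == normalize_code(item), , drop = FALSE]
    if (!nrow(row)) stopf("unknown item code: %s", item)
    item <- row
  }
  if (is.null(description)) description <- edit_item_description(item$description)
  paste0(
    "You are a scientific researcher writing a research paper for ",
    "randomized clinical trials. From your research paper, please provide ",
    n, " different 1 sentence examples of the following: ", description,
    ". For each example, also provide an example preceding sentence and ",
    "an example trailing sentence. Vary the sentence structure and ",
    "sentence complexity for each example. Also, vary the use of ",
    "introductory prepositional phrases in all examples")
}

#' Edit a checklist item description for generative prompting
#'
#' Applies, in order: replace `"with reasons"` with `"with specifics"`;
#' delete the hedges `"when applicable"` and `"if relevant"`; delete
#' `"such as ..."` example spans (to the closing parenthesis or the next
#' comma); then normalize doubled spaces and dangling commas.
#'
#' @param description Item description string.
#' @return The edited description.
#' @export
#' @examples
#' edit_item_description(paste0("Important changes to methods after trial ",
#'   "commencement (such as eligibility criteria), with reasons"))
edit_item_description <- function(description) {
  d <- description
  d <- gsub("with reasons", "with specifics", d, fixed = TRUE)
  # hedges: a sentence-initial hedge takes its trailing comma, an embedded
  # one takes its leading comma, so exactly one comma survives
  d <- gsub("(?i)^when applicable,?\\s*", "", d, perl = TRUE)
  d <- gsub("(?i)^if relevant,?\\s*", "", d, perl = TRUE)
  d <- gsub("(?i),\\s*when applicable", "", d, perl = TRUE)
  d <- gsub("(?i),\\s*if relevant", "", d, perl = TRUE)
  d <- gsub("(?i)\\s*when applicable,?", "", d, perl = TRUE)
  d <- gsub("(?i)\\s*if relevant,?", "", d, perl = TRUE)
  d <- gsub("\\s*\\(such as [^)]*\\)", "", d)
  d <- gsub(",?\\s*such as [^,)]*", "", d)
  d <- squeeze_ws(d)
  d <- gsub("\\s+,", ",", d)
  d <- gsub(",\\s*,", ",", d)
  d <- gsub("^[, ]+|[, ]+$", "", d)
  d
}

#' Parse an augmentation completion into instances
#'
#' Parses numbered response blocks of the form
#' \preformatted{1. Preceding: ...
#' Sentence: ...
#' Trailing: ...}
#' into augmentation instances. Rephrased instances inherit the original
#' instance's label; generative instances receive the label of the item
#' description used in the prompt. Malformed blocks are skipped with a
#' warning.
#'
#' @param text Completion text.
#' @param label Item code assigned to the parsed instances.
#' @param method `"llm_rephrase"` or `"llm_generative"`.
#' @param source_id Identifier of the originating sentence or prompt.
#' @param section_path Section path stored on the instances (a canonical
#'   header for the item's section group by default).
#' @return A `consort_augmentation` data frame (possibly empty).
#' @export
parse_augmentation_response <- function(text, label,
                                        method = c("llm_rephrase", "llm_generative"),
                                        source_id = "prompt",
                                        section_path = NULL) {
  method <- match.arg(method)
  label <- normalize_code(label)
  if (is.null(section_path)) {
    items <- consort_checklist()
    grp <- items$section_group[items$code == label]
    section_path <- if (length(grp)) grp[1] else ""
  }
  empty <- data.frame(method = character(0), source_article_id = character(0),
                      source_id = character(0), preceding = character(0),
                      target = character(0), trailing = character(0),
                      label = character(0), section_path = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("consort_augmentation", "data.frame")
  if (!is_string(text) || !nzchar(trim(text))) {
    warnf("empty augmentation response; no instances parsed")
    return(empty)
  }
  blocks <- strsplit(text, "(?m)^\\s*\\d+[.)]\\s*", perl = TRUE)[[1]]
  blocks <- blocks[nzchar(trim(blocks))]
  grab <- function(block, field) {
    m <- regmatches(block, regexec(
      paste0("(?im)^\\s*", field, "\\s*:\\s*(.+?)\\s*$"), block, perl = TRUE))[[1]]
    if (length(m) == 2L) trim(m[2]) else NA_character_
  }
  rows <- list()
  skipped <- 0L
  for (b in blocks) {
    pre <- grab(b, "Preceding(?: sentence)?")
    tgt <- grab(b, "(?:Sentence|Rephrased(?: sentence)?|Example)")
    tra <- grab(b, "Trailing(?: sentence)?")
    if (is.na(tgt) || !nzchar(tgt)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      method = method, source_article_id = NA_character_,
      source_id = source_id,
      preceding = if (is.na(pre)) "" else pre, target = tgt,
      trailing = if (is.na(tra)) "" else tra,
      label = label, section_path = section_path, stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warnf("skipped %d malformed augmentation block(s)", skipped)
  }
  if (!length(rows)) {
    if (skipped == 0L) warnf("no parsable augmentation blocks in response")
    return(empty)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("consort_augmentation", "data.frame")
  out
}

#' Accumulate generative augmentation instances
#'
#' Repeatedly prompts a completion provider with the generative template
#' until at least `target_total` instances have been collected (or the
#' iteration cap is hit, with a warning).
#'
#' @param provider Function `prompt -> completion text`.
#' @param item Checklist item (row or code) to generate for.
#' @param batch_n Examples requested per prompt (6 or 8).
#' @param target_total Total instances to accumulate (default 100).
#' @param max_iter Iteration cap (default 50).
#' @return A `consort_augmentation` data frame with an attribute `calls`
#'   recording the number of provider calls.
#' @export
accumulate_generative <- function(provider, item, batch_n = 8L,
                                  target_total = 100L, max_iter = 50L) {
  if (!is.function(provider)) stopf("provider must be a function")
  if (is.character(item)) {
    items <- consort_checklist()
    item <- items[items$code == normalize_code(item), , drop = FALSE]
    if (!nrow(item)) stopf("unknown item code")
  }
  prompt <- build_generative_prompt(item, n = batch_n)
  collected <- NULL
  calls <- 0L
  while ((is.null(collected) || nrow(collected) < target_total) &&
         calls < max_iter) {
    calls <- calls + 1L
    resp <- provider(prompt)
    inst <- parse_augmentation_response(
      resp, label = item$code, method = "llm_generative",
      source_id = sprintf("generative:%s:%d", item$code, calls))
    collected <- if (is.null(collected)) inst else rbind(collected, inst)
  }
  if (is.null(collected)) collected <- parse_augmentation_response("", item$code,
                                                                   "llm_generative")
  if (nrow(collected) < target_total) {
    warnf("iteration cap reached with %d/%d instances accumulated",
          nrow(collected), target_total)
  }
  class(collected) <- c("consort_augmentation", "data.frame")
  attr(collected, "calls") <- calls
  collected
}
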