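# Rule-based article-level checks for checklist items 1a and 1b.
#
# 1a: is the study described as randomized in the title? Case-insensitive
#     substring search for the stems "random", "randomis", "randomiz"
#     (substring, not word-boundary, so "randomization", "randomised" etc.
#     all match; "random" is a prefix of the other two stems, so any match
#     of those also matches "random" — the redundancy is harmless and the
#     reported evidence is the first matching stem).
# 1b: is the abstract structured? True iff the abstract starts with a
#     structured-abstract section label from the (configurable) NLM-style
#     header list.

TITLE_STEMS <- c("random", "randomis", "randomiz")

.rules_cache <- new.env(parent = emptyenv())

#' Check whether a title identifies a randomized trial (item 1a)
#'
#' @param title Article title (empty allowed).
#' @return List with `match` (logical) and `evidence` (the matched stem, or
#'   `""`).
#' @export
#' @examples
#' check_title_randomized("A Randomized Controlled Trial of X")$match  # TRUE
check_title_randomized <- function(title) {
  t <- tolower(trim(title %||% ""))
  for (stem in TITLE_STEMS) {
    if (grepl(stem, t, fixed = TRUE)) {
      return(list(match = TRUE, evidence = stem))
    }
  }
  list(match = FALSE, evidence = "")
}

#' Load the structured-abstract header list
#'
#' Reads the packaged list of structured-abstract section labels (a curated
#' synthetic stand-in for the National Library of Medicine label list; pass
#' `path` to use the full NLM list instead). Entries are uppercased,
#' deduplicated, and stripped of trailing punctuation.
#'
#' @param path Optional path to an alternative list (one header per line,
#'   `#` comments allowed).
#' @return Character vector of uppercase headers.
#' @export
load_structured_header_list <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache) {
    cached <- get0("headers", .rules_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "nlm_abstract_headers_synthetic.txt",
                        package = "consortcheck", mustWork = FALSE)
    if (!nzchar(path) || !file.exists(path)) {
      stopf("packaged structured-abstract header list not found")
    }
  } else if (!file.exists(path)) {
    stopf("header list not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trim(lines[!grepl("^\\s*#", lines)])
  headers <- unique(toupper(gsub("[[:punct:]]+$", "", lines[nzchar(lines)])))
  if (!length(headers)) stopf("header list %s is empty", path)
  if (use_cache) assign("headers", headers, .rules_cache)
  headers
}

#' Check whether an abstract is structured (item 1b)
#'
#' True iff the abstract's leading token sequence — the text before the
#' first colon or period (or the first word if neither occurs early) —
#' uppercased and stripped of the trailing delimiter, equals a listed
#' structured-abstract header.
#'
#' @param abstract_sentences Character vector of abstract sentences (or one
#'   abstract string); only the start of the abstract is examined.
#' @param headers Header list; defaults to [load_structured_header_list()].
#' @return List with `match` (logical) and `evidence` (the matched
#'   uppercase header, or `""`).
#' @export
check_structured_abstract <- function(abstract_sentences, headers = NULL) {
  headers <- headers %||% load_structured_header_list()
  first <- trim(abstract_sentences[nzchar(trim(abstract_sentences))][1] %||% "")
  if (is.na(first) || !nzchar(first)) return(list(match = FALSE, evidence = ""))
  lead <- regmatches(first, regexec("^([^:.]{1,60})[:.]", first))[[1]]
  candidate <- if (length(lead) == 2L) lead[2] else
    regmatches(first, regexec("^(\\S+)", first))[[1]][2]
  candidate <- toupper(trim(squeeze_ws(candidate %||% "")))
  if (nzchar(candidate) && candidate %in% headers) {
    list(match = TRUE, evidence = candidate)
  } else {
    list(match = FALSE, evidence = "")
  }
}

#' Article-level rule results for items 1a and 1b
#'
#' Applies [check_title_randomized()] and [check_structured_abstract()] to
#' each article of a corpus.
#'
#' @param corpus A `consort_corpus` data frame (uses the `title` and
#'   `abstract` parts).
#' @param headers Optional header list for the 1b check.
#' @return Data frame with one row per article: `article_id`, `item_1a`,
#'   `evidence_1a`, `item_1b`, `evidence_1b`.
#' @export
article_rules <- function(corpus, headers = NULL) {
  ids <- unique(corpus$article_id)
  out <- lapply(ids, function(id) {
    r1a <- check_title_randomized(article_title(corpus, id))
    abs_rows <- corpus$article_id == id & corpus$part == "abstract"
    abs_sent <- corpus$text[abs_rows][order(corpus$sentence_index[abs_rows])]
    r1b <- check_structured_abstract(
      if (length(abs_sent)) abs_sent else "", headers)
    data.frame(article_id = id,
               item_1a = r1a$match, evidence_1a = r1a$evidence,
               item_1b = r1b$match, evidence_1b = r1b$evidence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
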