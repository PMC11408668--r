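# JATS-style full-text XML ingestion.
#
# Extracts title, abstract and body sentences from PubMed-Central-style XML.
# Sentence segmentation is delegated to a configurable splitter; the default
# is a rule-based splitter on terminal punctuation followed by an
# uppercase/digit sentence opener (abbreviation-tolerant enough for fixtures
# and screening use, replaceable for production corpora).

#' Default rule-based sentence splitter
#'
#' Splits text at `.`, `!` or `?` followed by whitespace and an uppercase
#' letter, digit or opening bracket. Common abbreviations (e.g., "et al.",
#' "Fig.", "vs.") are protected.
#'
#' @param text A character scalar.
#' @return Character vector of sentences (no empty strings).
#' @export
default_sentence_splitter <- function(text) {
  text <- squeeze_ws(trim(text))
  if (!nzchar(text)) return(character(0))
  protected <- c("et al\\.", "Fig\\.", "Figs\\.", "vs\\.", "e\\.g\\.",
                 "i\\.e\\.", "Dr\\.", "No\\.", "approx\\.")
  for (p in protected) {
    text <- gsub(p, gsub("\\\\\\.", "<DOT>", p), text)
  }
  parts <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z0-9(“\"])", perl = TRUE)[[1]]
  parts <- gsub("<DOT>", ".", parts, fixed = TRUE)
  trim(parts[nzchar(trim(parts))])
}

#' Read a JATS-style XML full text
#'
#' Parses a PubMed-Central-style XML article into the sentence-level corpus
#' schema. The section path of each body sentence is built from the nested
#' `<sec><title>` elements, outermost first. Sentences are numbered 0-based
#' across title, abstract and body in reading order.
#'
#' @param path XML file.
#' @param article_id Identifier for the article; defaults to the file name
#'   without extension.
#' @param splitter Sentence segmentation function (character scalar ->
#'   character vector); defaults to [default_sentence_splitter()].
#' @return A single-article `consort_corpus` data frame (labels empty).
#' @export
read_jats_xml <- function(path, article_id = NULL,
                          splitter = default_sentence_splitter) {
  if (!file.exists(path)) stopf("XML file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stopf("malformed XML in %s: %s", path, conditionMessage(e)))
  if (is.null(article_id)) {
    article_id <- tools::file_path_sans_ext(basename(path))
  }

  title_node <- xml2::xml_find_first(doc, ".//front//article-title")
  if (is.na(title_node)) title_node <- xml2::xml_find_first(doc, ".//article-title")
  title <- if (is.na(title_node)) "" else squeeze_ws(trim(xml2::xml_text(title_node)))

  rows <- list()
  idx <- 0L
  add_row <- function(part, section_path, text) {
    rows[[length(rows) + 1L]] <<- data.frame(
      article_id = article_id, sentence_index = idx, part = part,
      section_path = section_path, text = text, labels = "",
      stringsAsFactors = FALSE)
    idx <<- idx + 1L
  }

  if (nzchar(title)) add_row("title", "", title)

  abstract <- xml2::xml_find_first(doc, ".//front//abstract")
  if (is.na(abstract)) abstract <- xml2::xml_find_first(doc, ".//abstract")
  if (!is.na(abstract)) {
    for (p in xml2::xml_find_all(abstract, ".//p")) {
      for (s in splitter(xml2::xml_text(p))) add_row("abstract", "", s)
    }
  }

  body <- xml2::xml_find_first(doc, ".//body")
  if (is.na(body)) {
    warnf("XML %s has no <body>; body sentences will be empty", path)
  } else {
    walk_sec <- function(node, path_so_far) {
      for (child in xml2::xml_children(node)) {
        name <- xml2::xml_name(child)
        if (name == "sec") {
          sec_title <- xml2::xml_find_first(child, "./title")
          header <- if (is.na(sec_title)) "" else
            squeeze_ws(trim(xml2::xml_text(sec_title)))
          walk_sec(child, c(path_so_far, header[nzchar(header)]))
        } else if (name == "p") {
          joined <- paste(path_so_far, collapse = ">")
          for (s in splitter(xml2::xml_text(child))) add_row("body", joined, s)
        }
      }
    }
    walk_sec(body, character(0))
  }

  if (!length(rows)) stopf("XML %s yielded no sentences", path)
  new_corpus(do.call(rbind, rows))
}
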