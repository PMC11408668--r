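# Classifier input assembly: header-prefixed context windows and sentence
# position features. A window never crosses an article boundary; missing
# neighbours are kept as empty segments so the segment layout is stable.

#' Prepend section headers to a sentence
#'
#' Builds the header-prefixed form of a sentence: the section headers of the
#' enclosing (nested) sections, followed by a space and the sentence text
#' (e.g., `"Methods Patients <sentence>"`).
#'
#' @param text Sentence text.
#' @param section_path Character vector of nested headers, outermost first
#'   (or a single `">"`-joined string).
#' @param mode `"none"` (text unchanged), `"innermost"` or `"outermost"`
#'   (one header), or `"all"` (full path outermost to innermost).
#' @return The prefixed sentence string.
#' @export
#' @examples
#' prefix_with_headers("Adults were eligible.", c("Methods", "Patients"), "all")
prefix_with_headers <- function(text, section_path,
                                mode = c("all", "none", "innermost", "outermost")) {
  mode <- match.arg(mode)
  if (length(section_path) == 1L && grepl(">", section_path, fixed = TRUE)) {
    section_path <- split_path(section_path)[[1]]
  }
  section_path <- section_path[nzchar(section_path)]
  if (mode == "none" || !length(section_path)) return(text)
  header <- switch(mode,
    all = paste(section_path, collapse = " "),
    innermost = section_path[length(section_path)],
    outermost = section_path[1])
  paste(header, text)
}

#' Context window around one sentence of an article
#'
#' Returns the preceding, target and trailing sentences at position `i`
#' (0-based) of an article. Neighbours outside the article are empty strings;
#' windows never cross article boundaries.
#'
#' @param article A single-article `consort_corpus` slice.
#' @param i 0-based sentence index within the article.
#' @return A list of class `consort_window` with elements `preceding`,
#'   `target`, `trailing` and the three rows' section paths.
#' @export
build_context_window <- function(article, i) {
  article <- article[order(article$sentence_index), , drop = FALSE]
  n <- nrow(article)
  pos <- match(i, article$sentence_index)
  if (is.na(pos)) {
    stopf("sentence index %s out of range (article has indices %s..%s)",
          i, min(article$sentence_index), max(article$sentence_index))
  }
  take <- function(j, col) if (j >= 1L && j <= n) article[[col]][j] else ""
  structure(list(
    preceding = take(pos - 1L, "text"),
    target = article$text[pos],
    trailing = take(pos + 1L, "text"),
    preceding_path = take(pos - 1L, "section_path"),
    target_path = article$section_path[pos],
    trailing_path = take(pos + 1L, "section_path")
  ), class = "consort_window")
}

#' Assemble the encoder input for a window
#'
#' Produces the ordered segment list fed to the text encoder: one segment
#' (target only) when context is off, three segments (preceding, target,
#' trailing) when on, each prefixed with its own section headers per
#' `header_mode`. The encoder adapter joins segments with its separator
#' token and prepends its classification marker; empty neighbours stay as
#' empty segments so the layout is fixed.
#'
#' @param window A `consort_window` from [build_context_window()].
#' @param context Logical; include the neighbouring sentences?
#' @param header_mode Passed to [prefix_with_headers()].
#' @param position A position feature from [relative_position_bin()] /
#'   [absolute_position_feature()], or `NULL`.
#' @return A list of class `consort_encoder_input` with `segments`
#'   (character vector of length 1 or 3) and `position`.
#' @export
assemble_input <- function(window, context = TRUE, header_mode = "all",
                           position = NULL) {
  pref <- function(text, path) {
    if (!nzchar(text)) "" else prefix_with_headers(text, path, header_mode)
  }
  segments <- if (isTRUE(context)) {
    c(pref(window$preceding, window$preceding_path),
      pref(window$target, window$target_path),
      pref(window$trailing, window$trailing_path))
  } else {
    pref(window$target, window$target_path)
  }
  structure(list(segments = segments, position = position),
            class = "consort_encoder_input")
}

#' Relative sentence position bin
#'
#' Maps a 0-based sentence index to one of 10 relative-position bins
#' (0-0.1, 0.1-0.2, ..., 0.9-1.0). The relative position is
#' `index / (n_sentences - 1)` so the final sentence of an article falls in
#' the last bin; bins are half-open with the last bin closed.
#'
#' @param index 0-based sentence index.
#' @param n_sentences Number of sentences in the article (>= 1).
#' @return Integer bin in `0:9` (vectorized over `index`).
#' @export
relative_position_bin <- function(index, n_sentences) {
  if (any(n_sentences < 1L)) stopf("n_sentences must be >= 1")
  if (any(index < 0L) || any(index >= n_sentences)) {
    stopf("index must satisfy 0 <= index < n_sentences")
  }
  denom <- rep_len(n_sentences, length(index)) - 1
  rel <- ifelse(denom > 0, index / pmax(denom, 1), 0)
  pmin(as.integer(floor(rel / 0.1)), 9L)
}

#' Absolute sentence position feature
#'
#' @param index 0-based sentence index.
#' @param cap Maximum encodable position (positions beyond it are clipped);
#'   default 512.
#' @return A list of class `consort_position` with `kind = "absolute"` and
#'   the (possibly clipped) `value`.
#' @export
absolute_position_feature <- function(index, cap = 512L) {
  if (any(index < 0L)) stopf("index must be non-negative")
  structure(list(kind = "absolute", value = pmin(as.integer(index), as.integer(cap))),
            class = "consort_position")
}

# Build all windows + encoder inputs for a corpus under one configuration.
# Returns a data frame with segments kept as a character matrix attribute.
assemble_corpus_inputs <- function(corpus, context, header_mode, position_kind,
                                   position_cap = 512L) {
  corpus <- corpus[order(corpus$article_id, corpus$sentence_index), ,
                   drop = FALSE]
  n <- nrow(corpus)
  nseg <- if (context) 3L else 1L
  segs <- matrix("", nrow = n, ncol = nseg)
  posval <- integer(n)
  row0 <- 1L
  for (a in split(seq_len(n), corpus$article_id)) {
    art <- corpus[a, , drop = FALSE]
    m <- length(a)
    for (j in seq_len(m)) {
      w <- list(
        preceding = if (j > 1L) art$text[j - 1L] else "",
        target = art$text[j],
        trailing = if (j < m) art$text[j + 1L] else "",
        preceding_path = if (j > 1L) art$section_path[j - 1L] else "",
        target_path = art$section_path[j],
        trailing_path = if (j < m) art$section_path[j + 1L] else ""
      )
      inp <- assemble_input(w, context = context, header_mode = header_mode)
      segs[a[j], ] <- inp$segments
      posval[a[j]] <- switch(position_kind,
        none = 0L,
        absolute = absolute_position_feature(art$sentence_index[j],
                                             position_cap)$value,
        relative = relative_position_bin(j - 1L, m))
    }
    row0 <- row0 + m
  }
  list(corpus = corpus, segments = segs, position = posval)
}
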