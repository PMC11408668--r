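# Sentence-level corpus container and I/O.
#
# The in-memory corpus is one base-R data frame (class `consort_corpus`),
# one row per sentence, columns:
#   article_id     chr
#   sentence_index int, 0-based, a single stream over title+abstract+body
#   part           chr: "title" | "abstract" | "body"
#   section_path   chr, nested headers joined with ">" (outermost first)
#   text           chr, non-empty
#   labels         chr, item codes joined with "|" ("" = unlabelled)
# An "article" is the slice of rows sharing an article_id.

CORPUS_COLUMNS <- c("article_id", "sentence_index", "part", "section_path",
                    "text", "labels")

new_corpus <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("consort_corpus", "data.frame")
  df
}

validate_corpus <- function(df, source = "corpus") {
  missing <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing)) {
    stopf("%s is missing required column(s): %s", source,
          paste(missing, collapse = ", "))
  }
  if (any(!nzchar(df$text) | is.na(df$text))) {
    stopf("%s contains empty sentence text (row %d)", source,
          which(!nzchar(df$text) | is.na(df$text))[1])
  }
  if (!all(df$part %in% c("title", "abstract", "body"))) {
    stopf("%s has invalid 'part' values (expected title/abstract/body)", source)
  }
  labs <- split_labels(df$labels)
  known <- sentence_level_items()$code
  bad <- setdiff(unique(unlist(labs)), known)
  if (length(bad)) {
    row <- which(vapply(labs, function(l) any(l %in% bad), logical(1)))[1]
    stopf("%s row %d: unknown item code(s): %s", source, row,
          paste(bad, collapse = ", "))
  }
  dup <- duplicated(df[, c("article_id", "sentence_index")])
  if (any(dup)) {
    stopf("%s: duplicated sentence_index within article %s", source,
          df$article_id[which(dup)[1]])
  }
  invisible(df)
}

#' Read a sentence-level corpus
#'
#' Reads the documented corpus schema: columns `article_id`,
#' `sentence_index` (0-based), `part` (title/abstract/body), `section_path`
#' (headers joined with `>`), `text`, and `labels` (item codes joined with
#' `|`, empty allowed). Label codes are normalized to lowercase and
#' validated against the sentence-level checklist; unknown codes are a
#' parse error.
#'
#' @param path File to read.
#' @param format `"csv"` or `"jsonl"` (one JSON object per sentence with the
#'   same fields). Defaults to the file extension.
#' @return A `consort_corpus` data frame ordered by article and sentence
#'   index.
#' @seealso [write_corpus()], [corpus_stats()], [read_jats_xml()]
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("jsonl", "ndjson"))
      "jsonl" else "csv"
  }
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    recs <- lapply(readLines(path, warn = FALSE), function(l) {
      if (!nzchar(trim(l))) NULL else jsonlite::fromJSON(l)
    })
    recs <- Filter(Negate(is.null), recs)
    do.call(rbind, lapply(recs, function(r)
      as.data.frame(r[CORPUS_COLUMNS], stringsAsFactors = FALSE)))
  }
  if (is.null(df) || !nrow(df)) stopf("corpus file %s is empty", path)
  missing <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing)) {
    stopf("corpus file %s is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df <- df[, CORPUS_COLUMNS]
  df$sentence_index <- as.integer(df$sentence_index)
  df$labels <- join_labels(lapply(split_labels(df$labels), normalize_code))
  df[is.na(df$section_path), "section_path"] <- ""
  validate_corpus(df, source = sprintf("corpus file %s", path))
  df <- df[order(df$article_id, df$sentence_index), ]
  new_corpus(df)
}

#' Write a sentence-level corpus
#'
#' Inverse of [read_corpus()]; round-trips all sentence fields.
#'
#' @param corpus A `consort_corpus` data frame.
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  df <- as.data.frame(corpus)[, CORPUS_COLUMNS]
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Split a corpus into articles
#'
#' @param corpus A `consort_corpus` data frame.
#' @return Named list of per-article `consort_corpus` slices, rows ordered by
#'   sentence index.
#' @export
articles <- function(corpus) {
  lapply(split(as.data.frame(corpus), corpus$article_id), function(a)
    new_corpus(a[order(a$sentence_index), ]))
}

#' Title of one article
#'
#' @param corpus A `consort_corpus` data frame.
#' @param article_id Article identifier.
#' @return The article's title (the `part == "title"` sentence), or `""` if
#'   the article has no title row.
#' @export
article_title <- function(corpus, article_id) {
  rows <- corpus$article_id == article_id & corpus$part == "title"
  if (!any(rows)) "" else corpus$text[rows][1]
}

#' Descriptive corpus statistics
#'
#' Counts articles, sentences, labelled sentences and label instances, and
#' the mean number of distinct checklist items per article.
#'
#' @param corpus A `consort_corpus` data frame (may be empty).
#' @return A list of class `consort_corpus_stats` with fields `n_articles`,
#'   `n_sentences`, `n_labeled_sentences`, `n_label_instances`,
#'   `mean_items_per_article`.
#' @export
corpus_stats <- function(corpus) {
  labs <- split_labels(corpus$labels)
  n_per <- lengths(labs)
  per_article_items <- if (nrow(corpus)) {
    vapply(split(labs, corpus$article_id),
           function(l) length(unique(unlist(l))), integer(1))
  } else integer(0)
  out <- list(
    n_articles = length(unique(corpus$article_id)),
    n_sentences = nrow(corpus),
    n_labeled_sentences = sum(n_per > 0L),
    n_label_instances = sum(n_per),
    mean_items_per_article = if (length(per_article_items))
      mean(per_article_items) else 0
  )
  class(out) <- "consort_corpus_stats"
  out
}

#' @export
print.consort_corpus_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Corpus: %d articles, %d sentences\n",
    "  labelled sentences : %d (%.1f%%)\n",
    "  label instances    : %d\n",
    "  mean items/article : %.1f\n"),
    x$n_articles, x$n_sentences, x$n_labeled_sentences,
    if (x$n_sentences) 100 * x$n_labeled_sentences / x$n_sentences else 0,
    x$n_label_instances, x$mean_items_per_article))
  invisible(x)
}

#' Write sentence predictions
#'
#' Serializes predictions as JSON Lines: a header record with the label set,
#' then one record per sentence carrying the per-label probabilities (at full
#' double precision) and the thresholded label set.
#'
#' @param predictions A `consort_predictions` data frame from
#'   [predict.consort_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [read_predictions()]
#' @export
write_predictions <- function(predictions, path) {
  label_set <- attr(predictions, "label_set")
  if (is.null(label_set)) stopf("predictions carry no label_set attribute")
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    list(record = "header", label_set = label_set,
         threshold = attr(predictions, "threshold")),
    auto_unbox = TRUE, digits = NA), con)
  pcols <- paste0("p_", label_set)
  for (i in seq_len(nrow(predictions))) {
    rec <- list(
      article_id = predictions$article_id[i],
      sentence_index = predictions$sentence_index[i],
      probabilities = as.numeric(predictions[i, pcols]),
      predicted_labels = split_labels(predictions$predicted[i])[[1]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read sentence predictions written by [write_predictions()]
#'
#' @param path File to read.
#' @return A `consort_predictions` data frame.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trim(lines))]
  if (!length(lines)) stopf("prediction file %s has no header record", path)
  header <- jsonlite::fromJSON(lines[1])
  label_set <- header$label_set
  rows <- lapply(lines[-1], jsonlite::fromJSON)
  probs <- do.call(rbind, lapply(rows, function(r) as.numeric(r$probabilities)))
  df <- data.frame(
    article_id = vapply(rows, function(r) as.character(r$article_id), character(1)),
    sentence_index = vapply(rows, function(r) as.integer(r$sentence_index), integer(1)),
    predicted = vapply(rows, function(r)
      paste(unlist(r$predicted_labels), collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  )
  if (length(rows)) {
    colnames(probs) <- paste0("p_", label_set)
    df <- cbind(df, as.data.frame(probs))
  } else {
    for (l in label_set) df[[paste0("p_", l)]] <- numeric(0)
  }
  new_predictions(df, label_set, threshold = header$threshold %||% 0.5)
}

new_predictions <- function(df, label_set, threshold = 0.5) {
  rownames(df) <- NULL
  attr(df, "label_set") <- label_set
  attr(df, "threshold") <- threshold
  class(df) <- c("consort_predictions", "data.frame")
  df
}
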