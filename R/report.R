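# Per-article checklist reports for screening use.

#' Build a per-article checklist report
#'
#' Combines thresholded sentence predictions with the article-level rule
#' results into a screening report: each sentence-level item is `reported`
#' iff at least one sentence is predicted for it (with the supporting
#' sentences ordered by probability, descending), items 1a/1b take the
#' rule results with their evidence, and item 2a is shown as
#' `not assessed` (deliberately excluded from sentence classification).
#'
#' @param article A single-article `consort_corpus` slice.
#' @param predictions `consort_predictions` covering every sentence of the
#'   article.
#' @param rule_results One row of [article_rules()] output for the article
#'   (computed from the article if omitted).
#' @return A list of class `consort_report`: `article_id`, `items` (one
#'   entry per checklist item, ordered by code, each with `status` and
#'   `supporting`), and the 1a/1b evidence.
#' @export
build_report <- function(article, predictions, rule_results = NULL) {
  id <- unique(article$article_id)
  if (length(id) != 1L) stopf("build_report expects a single article")
  preds <- predictions[predictions$article_id == id, , drop = FALSE]
  missing <- setdiff(article$sentence_index, preds$sentence_index)
  if (length(missing)) {
    stopf("predictions do not cover sentence(s) %s of article %s",
          paste(head(missing, 5), collapse = ", "), id)
  }
  if (is.null(rule_results)) {
    rule_results <- article_rules(article)
  }
  rr <- rule_results[rule_results$article_id == id, , drop = FALSE]
  if (!nrow(rr)) stopf("rule_results carry no row for article %s", id)

  label_set <- attr(predictions, "label_set")
  checklist <- consort_checklist()
  items <- vector("list", nrow(checklist))
  names(items) <- checklist$code
  pred_lists <- split_labels(preds$predicted)
  for (i in seq_len(nrow(checklist))) {
    code <- checklist$code[i]
    if (checklist$article_level[i]) {
      flag <- if (code == "1a") rr$item_1a else rr$item_1b
      evid <- if (code == "1a") rr$evidence_1a else rr$evidence_1b
      items[[i]] <- list(code = code, title = checklist$title[i],
                         status = if (flag) "reported" else "missing",
                         evidence = evid, supporting = list())
      next
    }
    if (!checklist$sentence_level[i]) {
      items[[i]] <- list(code = code, title = checklist$title[i],
                         status = "not assessed", supporting = list())
      next
    }
    hit <- which(vapply(pred_lists, function(l) code %in% l, logical(1)))
    if (!length(hit)) {
      items[[i]] <- list(code = code, title = checklist$title[i],
                         status = "missing", supporting = list())
      next
    }
    pcol <- paste0("p_", code)
    probs <- if (pcol %in% names(preds)) preds[[pcol]][hit] else
      rep(NA_real_, length(hit))
    ord <- order(probs, decreasing = TRUE)
    sup <- lapply(ord, function(j) {
      si <- preds$sentence_index[hit[j]]
      list(sentence_index = si,
           text = article$text[match(si, article$sentence_index)],
           probability = probs[j])
    })
    items[[i]] <- list(code = code, title = checklist$title[i],
                       status = "reported", supporting = sup)
  }
  structure(list(article_id = id, items = items,
                 item_1a = rr$item_1a, evidence_1a = rr$evidence_1a,
                 item_1b = rr$item_1b, evidence_1b = rr$evidence_1b),
            class = "consort_report")
}

#' @export
print.consort_report <- function(x, ...) {
  cat(format_report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a checklist report as Markdown
#'
#' @param report A `consort_report`.
#' @param max_supporting Supporting sentences shown per item.
#' @return Character vector of Markdown lines.
#' @export
format_report_markdown <- function(report, max_supporting = 2L) {
  lines <- c(sprintf("# CONSORT screening report: %s", report$article_id), "")
  n_rep <- sum(vapply(report$items, function(it)
    identical(it$status, "reported"), logical(1)))
  lines <- c(lines, sprintf("Reported items: %d of %d assessed.", n_rep,
                            sum(vapply(report$items, function(it)
                              it$status != "not assessed", logical(1)))), "")
  for (it in report$items) {
    mark <- switch(it$status, reported = "x", missing = " ", "-")
    head_line <- sprintf("- [%s] %s %s — %s", mark, it$code, it$title,
                         it$status)
    if (!is.null(it$evidence) && nzchar(it$evidence %||% "")) {
      head_line <- sprintf("%s (evidence: %s)", head_line, it$evidence)
    }
    lines <- c(lines, head_line)
    for (s in head(it$supporting, max_supporting)) {
      lines <- c(lines, sprintf("    - s%d (p=%.2f): %s", s$sentence_index,
                                s$probability, s$text))
    }
  }
  lines
}

#' Serialize a checklist report to JSON
#'
#' @param report A `consort_report`.
#' @param path Output file; when `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
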