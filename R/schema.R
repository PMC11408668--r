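# CONSORT 2010 fine-grained item taxonomy.
#
# The checklist ships as a packaged tab-separated table (one row per item)
# so the item -> section mapping is data, not code, and can be overridden.

.schema_cache <- new.env(parent = emptyenv())

SECTION_GROUPS <- c("TitleAbstract", "Introduction", "Methods", "Results",
                    "Discussion", "OtherInformation")

#' Load the CONSORT 2010 checklist
#'
#' Returns the 37 fine-grained CONSORT checklist items with their codes,
#' short titles, descriptions, section groups and level flags. Items 1a
#' (randomized in title) and 1b (structured abstract) are article-level;
#' item 2a (Background) is excluded from sentence classification as a
#' category virtually all papers report; the remaining 34 items are
#' sentence-level. Eight sentence-level items are flagged `rare`
#' (augmentation-eligible).
#'
#' @param path Optional path to an alternative checklist table with the same
#'   tab-separated columns (`code`, `title`, `description`, `section_group`,
#'   `article_level`, `sentence_level`, `rare`). Defaults to the packaged
#'   table.
#' @return A data frame of class `consort_checklist`, one row per item,
#'   ordered by code.
#' @export
#' @examples
#' items <- consort_checklist()
#' nrow(items)                      # 37
#' sum(items$sentence_level)        # 34
consort_checklist <- function(path = NULL) {
  use_cache <- is.null(path)
  if (is.null(path)) {
    cached <- get0("checklist", .schema_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "consort_items.tsv",
                        package = "consortcheck", mustWork = FALSE)
    if (!nzchar(path) || !file.exists(path)) {
      stopf("packaged CONSORT item table not found; installation is corrupt")
    }
  } else if (!file.exists(path)) {
    stopf("checklist table not found: %s", path)
  }
  items <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      quote = "", comment.char = "#")
  required <- c("code", "title", "description", "section_group",
                "article_level", "sentence_level", "rare")
  missing <- setdiff(required, names(items))
  if (length(missing)) {
    stopf("checklist table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  items$code <- normalize_code(items$code)
  for (col in c("article_level", "sentence_level", "rare")) {
    items[[col]] <- as.logical(items[[col]])
  }
  if (anyDuplicated(items$code)) stopf("duplicate item codes in checklist table")
  bad <- setdiff(unique(items$section_group), SECTION_GROUPS)
  if (length(bad)) stopf("unknown section group(s): %s", paste(bad, collapse = ", "))
  items <- items[order_codes(items$code), , drop = FALSE]
  rownames(items) <- NULL
  class(items) <- c("consort_checklist", "data.frame")
  if (use_cache) assign("checklist", items, .schema_cache)
  items
}

# Deterministic checklist order: by item number, then sub-letter.
order_codes <- function(codes) {
  num <- as.integer(gsub("[a-z]", "", codes))
  sub <- gsub("[0-9]", "", codes)
  order(num, sub)
}

#' @export
print.consort_checklist <- function(x, ...) {
  cat(sprintf("CONSORT checklist: %d items (%d sentence-level, %d article-level, %d rare)\n",
              nrow(x), sum(x$sentence_level), sum(x$article_level), sum(x$rare)))
  print.data.frame(x[, c("code", "title", "section_group")], right = FALSE)
  invisible(x)
}

#' Sentence-level checklist items
#'
#' The 34 items used by the sentence classifier: the full checklist minus the
#' article-level items 1a and 1b and the excluded item 2a.
#'
#' @inheritParams consort_checklist
#' @return A `consort_checklist` data frame with 34 rows, in checklist order.
#' @export
sentence_level_items <- function(path = NULL) {
  items <- consort_checklist(path)
  out <- items[items$sentence_level, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rare (augmentation-eligible) item codes
#'
#' Codes of the checklist items with fewer than 100 labelled instances
#' corpus-wide, the targets of data augmentation: 3b, 6b, 7b, 9, 11b, 12b,
#' 14b and 21.
#'
#' @inheritParams consort_checklist
#' @return Character vector of 8 item codes.
#' @export
rare_items <- function(path = NULL) {
  items <- consort_checklist(path)
  items$code[items$rare]
}

#' Sentence-level items of one checklist section group
#'
#' @inheritParams consort_checklist
#' @param group One of `"TitleAbstract"`, `"Introduction"`, `"Methods"`,
#'   `"Results"`, `"Discussion"`, `"OtherInformation"`.
#' @return A `consort_checklist` data frame restricted to sentence-level
#'   items whose `section_group` equals `group` (empty for
#'   `"TitleAbstract"`, whose items are article-level).
#' @export
items_for_section_group <- function(group, path = NULL) {
  if (!is_string(group) || !(group %in% SECTION_GROUPS)) {
    stopf("unknown section group: %s (expected one of %s)",
          paste(group, collapse = ", "), paste(SECTION_GROUPS, collapse = ", "))
  }
  items <- sentence_level_items(path)
  out <- items[items$section_group == group, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Validate a vector of label codes against the sentence-level item set.
assert_known_codes <- function(codes, where = "labels") {
  known <- sentence_level_items()$code
  bad <- setdiff(unique(codes), known)
  if (length(bad)) {
    stopf("unknown item code(s) in %s: %s", where, paste(bad, collapse = ", "))
  }
  invisible(codes)
}
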