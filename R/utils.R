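# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), inherits = FALSE))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# "6a|11a" -> c("6a","11a"); "" -> character(0)
split_labels <- function(x) {
  x <- as.character(x)
  if (!length(x)) return(list())
  lapply(strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE),
         function(v) v[nzchar(v)])
}

join_labels <- function(lst) {
  vapply(lst, paste, character(1), collapse = "|")
}

split_path <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ">", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

join_path <- function(lst) {
  vapply(lst, paste, character(1), collapse = ">")
}

# Normalize an item code: lowercase alphanumeric ("3A " -> "3a").
normalize_code <- function(code) {
  gsub("[^a-z0-9]", "", tolower(trimws(as.character(code))))
}

trim <- function(x) gsub("^\\s+|\\s+$", "", x)

squeeze_ws <- function(x) gsub("\\s+", " ", x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
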