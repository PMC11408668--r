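# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny hand-built two-article corpus with known labels.
tiny_corpus <- function() {
  df <- data.frame(
    article_id = c(rep("a1", 6), rep("a2", 5)),
    sentence_index = c(0:5, 0:4),
    part = c("title", "abstract", "body", "body", "body", "body",
             "title", "abstract", "body", "body", "body"),
    section_path = c("", "", "Introduction", "Methods>Patients",
                     "Methods>Patients", "Results",
                     "", "", "Methods", "Methods>Statistical analysis",
                     "Discussion"),
    text = c("A randomized trial of things.",
             "Background: We did a trial.",
             "We aimed to assess things.",
             "Adults were eligible for inclusion.",
             "Participants received the drug weekly.",
             "Outcomes improved in the treatment group.",
             "An observational study of stuff.",
             "We describe a cohort.",
             "Eligibility required informed consent.",
             "Analyses used regression models.",
             "The trial has limitations."),
    labels = c("", "", "2b", "4a", "5", "17a",
               "", "", "4a", "12a", "20"),
    stringsAsFactors = FALSE)
  class(df) <- c("consort_corpus", "data.frame")
  df
}

# Small synthetic corpus for model tests (fast to fit).
small_cued_corpus <- function(n_articles = 4L, seed = 101L,
                              cue_strength = 1.0, ...) {
  generate_corpus(generator_spec(
    n_articles = n_articles, sentences_per_article = c(20L, 30L),
    cue_strength = cue_strength, seed = seed, ...))
}

fast_config <- function(...) {
  consort_config(encoder_dim = 256L, epochs = 8L, seed = 7L, ...)
}

# Brute-force metric enumerator: the independent oracle for micro/macro,
# article (ANY) and article (1+) metrics. Works unit by unit with explicit
# loops and no shared code with the package implementation.
brute_force_metrics <- function(gold, predictions, label_set) {
  gold_sets <- lapply(strsplit(gold$labels, "|", fixed = TRUE),
                      function(v) v[nzchar(v)])
  key <- paste(predictions$article_id, predictions$sentence_index)
  pred_sets <- lapply(strsplit(predictions$predicted, "|", fixed = TRUE),
                      function(v) v[nzchar(v)])
  pred_sets <- pred_sets[match(paste(gold$article_id, gold$sentence_index), key)]

  # sentence level
  tp <- fp <- fn <- setNames(numeric(length(label_set)), label_set)
  for (i in seq_len(nrow(gold))) {
    for (l in label_set) {
      g <- l %in% gold_sets[[i]]
      p <- l %in% pred_sets[[i]]
      if (g && p) tp[l] <- tp[l] + 1
      if (!g && p) fp[l] <- fp[l] + 1
      if (g && !p) fn[l] <- fn[l] + 1
    }
  }
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  micro <- prf(sum(tp), sum(fp), sum(fn))
  active <- (tp + fp + fn) > 0
  per_f1 <- vapply(label_set, function(l) prf(tp[l], fp[l], fn[l])[3],
                   numeric(1))
  macro <- if (any(active)) mean(per_f1[active]) else NA_real_

  # article level
  any_tp <- any_fp <- any_fn <- 0
  one_tp <- one_fp <- one_fn <- 0
  for (a in unique(gold$article_id)) {
    rows <- which(gold$article_id == a)
    for (l in label_set) {
      g_rows <- rows[vapply(rows, function(i) l %in% gold_sets[[i]], logical(1))]
      p_rows <- rows[vapply(rows, function(i) l %in% pred_sets[[i]], logical(1))]
      g <- length(g_rows) > 0; p <- length(p_rows) > 0
      if (g && p) any_tp <- any_tp + 1
      if (!g && p) any_fp <- any_fp + 1
      if (g && !p) any_fn <- any_fn + 1
      if (g && p && length(intersect(g_rows, p_rows)) > 0) {
        one_tp <- one_tp + 1
      } else if (g && p) {
        one_fp <- one_fp + 1; one_fn <- one_fn + 1
      } else {
        if (!g && p) one_fp <- one_fp + 1
        if (g && !p) one_fn <- one_fn + 1
      }
    }
  }
  list(micro = micro, macro_f1 = macro,
       any = prf(any_tp, any_fp, any_fn),
       one_plus = prf(one_tp, one_fp, one_fn))
}

# Random small gold/prediction pair for property tests.
random_eval_case <- function(label_set = c("a1", "b2", "c3", "d4")) {
  n_art <- sample(1:5, 1)
  rows <- list()
  for (a in seq_len(n_art)) {
    n_s <- sample(1:6, 1)
    for (s in seq_len(n_s)) {
      rows[[length(rows) + 1L]] <- data.frame(
        article_id = paste0("art", a), sentence_index = s - 1L,
        part = "body", section_path = "Methods",
        text = "x y z",
        labels = paste(sample(label_set, rbinom(1, 2, 0.3)), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  gold <- do.call(rbind, rows)
  pred <- data.frame(
    article_id = gold$article_id, sentence_index = gold$sentence_index,
    predicted = vapply(seq_len(nrow(gold)), function(i)
      paste(sample(label_set, rbinom(1, 2, 0.3)), collapse = "|"),
      character(1)),
    stringsAsFactors = FALSE)
  list(gold = gold, pred = pred, label_set = label_set)
}

# Canned completion text in the documented augmentation response format.
canned_response <- function(n, prefix = "Generated sentence") {
  paste(vapply(seq_len(n), function(i) sprintf(
    "%d. Preceding: Before sentence %d.\nSentence: %s %d.\nTrailing: After sentence %d.",
    i, i, prefix, i, i), character(1)), collapse = "\n\n")
}

# Minimal JATS-style XML fixture written to a temp file.
write_jats_fixture <- function(path, levels = 2L, with_abstract = TRUE) {
  sec3 <- if (levels >= 3L)
    "<sec><title>Subgroup</title><p>Deep text here. More deep text.</p></sec>"
  else ""
  inner <- if (levels >= 2L) sprintf(
    "<sec><title>Patients</title><p>Adults were eligible. Consent was obtained.</p>%s</sec>",
    sec3) else "<p>Adults were eligible. Consent was obtained.</p>"
  abstract <- if (with_abstract)
    "<abstract><p>Background: We did a trial. It was fine.</p></abstract>" else ""
  xml <- sprintf(
    '<?xml version="1.0"?>
<article>
  <front>
    <article-meta>
      <title-group><article-title>A randomized trial of X</article-title></title-group>
      %s
    </article-meta>
  </front>
  <body>
    <sec><title>Methods</title>%s</sec>
    <sec><title>Results</title><p>Outcomes improved. Effects were large.</p></sec>
  </body>
</article>', abstract, inner)
  writeLines(xml, path)
  path
}
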