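# Synthetic labelled RCT-like corpora.
#
# The generator emulates the statistical shape of a sentence-annotated RCT
# corpus: ~50 articles of one to a few hundred sentences with nested IMRaD
# section paths, multi-label sentence annotations over the 34 sentence-level
# items with strongly skewed frequencies (the 8 rare items well under 100
# instances corpus-wide), titles with or without randomized-trial wording,
# and structured or unstructured abstracts. Each item owns one reserved cue
# token; a labelled sentence carries its items' cues with probability
# `cue_strength`, which makes separability controllable (1.0 = fully cued,
# 0 = label-free noise). The cue can instead be planted in a neighbouring
# sentence to probe the value of context windows. It makes no attempt to
# imitate real clinical prose.

.filler_vocab <- c(
  "patients", "participants", "adults", "children", "subjects", "group",
  "groups", "arm", "cohort", "treatment", "placebo", "intervention",
  "control", "dose", "weekly", "daily", "baseline", "followup", "visit",
  "clinic", "hospital", "centre", "site", "screening", "enrolment",
  "consent", "protocol", "assessment", "measurement", "questionnaire",
  "scale", "score", "outcome", "endpoint", "primary", "secondary",
  "analysis", "model", "regression", "estimate", "interval", "confidence",
  "difference", "mean", "median", "ratio", "risk", "effect", "significant",
  "observed", "reported", "recorded", "collected", "completed", "received",
  "administered", "allocated", "randomly", "blinded", "masked", "open",
  "label", "period", "weeks", "months", "years", "data", "results",
  "findings", "evidence", "study", "trial", "design", "criteria",
  "eligible", "excluded", "included", "withdrawn", "adverse", "events",
  "safety", "tolerability", "improvement", "reduction", "increase")

cue_token <- function(code) paste0("itemcue", code)

default_label_freq <- function() {
  items <- sentence_level_items()
  freq <- numeric(nrow(items))
  names(freq) <- items$code
  for (i in seq_len(nrow(items))) {
    g <- items$section_group[i]
    freq[i] <- if (items$rare[i]) {
      switch(g, Methods = 0.018, Results = 0.022, Discussion = 0.045, 0.02)
    } else {
      switch(g, Introduction = 0.20, Methods = 0.055, Results = 0.07,
             Discussion = 0.13, OtherInformation = 0.13, 0.05)
    }
  }
  freq
}

#' Synthetic corpus generator specification
#'
#' Collects the generator's knobs. The defaults emulate the shape of a
#' 50-article sentence-annotated RCT corpus: roughly 10,000 sentences,
#' close to half of them labelled, about 5,200 label instances, and each
#' rare item expected well under 100 instances corpus-wide.
#'
#' @param n_articles Number of articles (default 50).
#' @param sentences_per_article Range (min, max) of body sentences per
#'   article (default 100-300; a title and a 6-9-sentence abstract are
#'   added on top).
#' @param label_freq Named vector over the 34 sentence-level item codes:
#'   the probability that a sentence in the item's section group carries
#'   the item. Defaults per section group, skewed so the 8 rare items stay
#'   under 100 instances.
#' @param cue_strength Probability that a labelled sentence carries its
#'   item's reserved cue token (default 0.9).
#' @param cue_position Where the cue is planted: `"target"` (default), or
#'   `"preceding"`/`"trailing"`/`"neighbor"` to put it only in a
#'   neighbouring sentence (probing context windows).
#' @param multi_label_rate Probability that an already-labelled sentence
#'   receives one extra same-section label (default 0.08).
#' @param p_randomized_title Probability that a title uses randomized-trial
#'   wording (default 0.85).
#' @param p_structured_abstract Probability of a structured abstract
#'   (default 0.7).
#' @param seed RNG seed; generation is fully reproducible.
#' @return A list of class `consort_generator_spec`.
#' @export
generator_spec <- function(n_articles = 50L,
                           sentences_per_article = c(100L, 300L),
                           label_freq = default_label_freq(),
                           cue_strength = 0.9,
                           cue_position = c("target", "preceding",
                                            "trailing", "neighbor"),
                           multi_label_rate = 0.08,
                           p_randomized_title = 0.85,
                           p_structured_abstract = 0.7,
                           seed = 1L) {
  cue_position <- match.arg(cue_position)
  if (any(label_freq < 0 | label_freq > 1)) {
    stopf("label frequencies must lie in [0, 1]")
  }
  if (cue_strength < 0 || cue_strength > 1) {
    stopf("cue_strength must lie in [0, 1]")
  }
  items <- sentence_level_items()
  missing <- setdiff(items$code, names(label_freq))
  if (length(missing)) {
    stopf("label_freq is missing item(s): %s", paste(missing, collapse = ", "))
  }
  # infeasible when a section's expected labels per sentence is saturated
  for (g in unique(items$section_group)) {
    s <- sum(label_freq[items$code[items$section_group == g]])
    if (s > 3) {
      stopf("label frequencies in section group %s sum to %.2f (> 3); %s",
            g, s, "a sentence cannot plausibly carry that many items")
    }
  }
  structure(list(
    n_articles = as.integer(n_articles),
    sentences_per_article = as.integer(sentences_per_article),
    label_freq = label_freq, cue_strength = cue_strength,
    cue_position = cue_position, multi_label_rate = multi_label_rate,
    p_randomized_title = p_randomized_title,
    p_structured_abstract = p_structured_abstract,
    seed = as.integer(seed)
  ), class = "consort_generator_spec")
}

# Body section layout: share of body sentences and nested Methods
# subsections.
.section_layout <- list(
  list(group = "Introduction", share = 0.10, path = "Introduction",
       subs = character(0)),
  list(group = "Methods", share = 0.40, path = "Methods",
       subs = c("Participants", "Interventions", "Outcomes",
                "Randomisation", "Statistical analysis")),
  list(group = "Results", share = 0.30, path = "Results",
       subs = c("Participant flow", "Outcomes and estimation")),
  list(group = "Discussion", share = 0.15, path = "Discussion",
       subs = character(0)),
  list(group = "OtherInformation", share = 0.05, path = "Other information",
       subs = character(0))
)

random_words <- function(n) {
  .filler_vocab[sample.int(length(.filler_vocab), n, replace = TRUE)]
}

# filler words safe for titles: none may trigger the item-1a stems
.title_vocab <- grep("random", .filler_vocab, value = TRUE, invert = TRUE)

title_words <- function(n) {
  .title_vocab[sample.int(length(.title_vocab), n, replace = TRUE)]
}

make_title <- function(randomized) {
  x <- paste(title_words(2), collapse = " ")
  if (randomized) {
    tpl <- sample(c(
      "A randomized controlled trial of %s",
      "A randomised placebo-controlled study of %s",
      "Effects of %s: a cluster randomized trial",
      "Randomized evaluation of %s in adults"), 1)
  } else {
    tpl <- sample(c(
      "An observational cohort study of %s",
      "A cross-sectional survey of %s",
      "Prospective evaluation of %s in routine care"), 1)
  }
  sprintf(tpl, x)
}

make_abstract <- function(structured) {
  heads <- c("BACKGROUND", "METHODS", "RESULTS", "CONCLUSIONS")
  n_per <- sample(1:2, length(heads), replace = TRUE)
  sentences <- character(0)
  for (i in seq_along(heads)) {
    for (j in seq_len(n_per[i])) {
      body <- paste(random_words(sample(8:12, 1)), collapse = " ")
      lead <- if (structured && j == 1L) paste0(heads[i], ": ") else ""
      # an unstructured abstract must not open with a header token
      if (!structured && i == 1L && j == 1L) {
        body <- paste("We", body)
      }
      sentences <- c(sentences, paste0(lead, toupper(substr(body, 1, 1)),
                                       substr(body, 2, nchar(body)), "."))
    }
  }
  sentences
}

#' Generate a synthetic labelled corpus
#'
#' @param spec A [generator_spec()].
#' @return A `consort_corpus` data frame with an `article_truth` attribute
#'   (data frame of per-article gold values for the 1a/1b rules:
#'   `article_id`, `item_1a`, `item_1b`).
#' @export
generate_corpus <- function(spec = generator_spec()) {
  if (!inherits(spec, "consort_generator_spec")) {
    stopf("spec must come from generator_spec()")
  }
  items <- sentence_level_items()
  with_seed(spec$seed, {
    all_rows <- vector("list", spec$n_articles)
    truth <- vector("list", spec$n_articles)
    for (a in seq_len(spec$n_articles)) {
      id <- sprintf("art%03d", a)
      randomized <- runif(1) < spec$p_randomized_title
      structured <- runif(1) < spec$p_structured_abstract
      title <- make_title(randomized)
      abstract <- make_abstract(structured)

      n_body <- sample(spec$sentences_per_article[1]:
                       spec$sentences_per_article[2], 1)
      counts <- pmax(1L, round(n_body *
        vapply(.section_layout, function(s) s$share, numeric(1))))
      words <- list(); paths <- character(0); groups <- character(0)
      for (si in seq_along(.section_layout)) {
        sec <- .section_layout[[si]]
        n_s <- counts[si]
        subs <- sec$subs
        sub_of <- if (length(subs)) {
          sort(sample.int(length(subs), n_s, replace = TRUE))
        } else rep(0L, n_s)
        for (j in seq_len(n_s)) {
          words[[length(words) + 1L]] <-
            random_words(sample(8:14, 1))
          paths <- c(paths, if (sub_of[j] > 0L)
            paste(sec$path, subs[sub_of[j]], sep = ">") else sec$path)
          groups <- c(groups, sec$group)
        }
      }
      nb <- length(words)

      # label assignment: per item, Bernoulli over its section's sentences
      labels <- rep(list(character(0)), nb)
      for (i in seq_len(nrow(items))) {
        code <- items$code[i]
        eligible <- which(groups == items$section_group[i])
        if (!length(eligible)) next
        hit <- eligible[runif(length(eligible)) < spec$label_freq[code]]
        for (s in hit) labels[[s]] <- c(labels[[s]], code)
      }
      # optional extra same-section label on labelled sentences
      if (spec$multi_label_rate > 0) {
        for (s in which(lengths(labels) == 1L)) {
          if (runif(1) < spec$multi_label_rate) {
            pool <- setdiff(items$code[items$section_group == groups[s]],
                            labels[[s]])
            if (length(pool)) {
              labels[[s]] <- c(labels[[s]], pool[sample.int(length(pool), 1)])
            }
          }
        }
      }
      # cue insertion
      for (s in seq_len(nb)) {
        for (code in labels[[s]]) {
          if (runif(1) >= spec$cue_strength) next
          tgt <- switch(spec$cue_position,
            target = s,
            preceding = if (s > 1L) s - 1L else s + 1L,
            trailing = if (s < nb) s + 1L else s - 1L,
            neighbor = {
              opts <- c(if (s > 1L) s - 1L, if (s < nb) s + 1L)
              opts[sample.int(length(opts), 1)]
            })
          w <- words[[tgt]]
          at <- sample.int(length(w) + 1L, 1)
          words[[tgt]] <- append(w, cue_token(code), after = at - 1L)
        }
      }

      body_text <- vapply(words, function(w) {
        s <- paste(w, collapse = " ")
        paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)), ".")
      }, character(1))

      n_front <- 1L + length(abstract)
      rows <- data.frame(
        article_id = id,
        sentence_index = seq_len(n_front + nb) - 1L,
        part = c("title", rep("abstract", length(abstract)),
                 rep("body", nb)),
        section_path = c("", rep("", length(abstract)), paths),
        text = c(title, abstract, body_text),
        labels = c("", rep("", length(abstract)), join_labels(labels)),
        stringsAsFactors = FALSE)
      all_rows[[a]] <- rows
      truth[[a]] <- data.frame(article_id = id, item_1a = randomized,
                               item_1b = structured, stringsAsFactors = FALSE)
    }
    corpus <- new_corpus(do.call(rbind, all_rows))
    attr(corpus, "article_truth") <- do.call(rbind, truth)
    corpus
  })
}

#' Generate title/abstract fixtures for the 1a/1b rules
#'
#' Produces labelled fixtures stratified over the four truth combinations:
#' titles with and without randomized-trial stems (covering case and
#' spelling variants), abstracts with and without a leading structured
#' header (covering the colon and period delimiters).
#'
#' @param n Number of fixtures (>= 1; both truth values of both items are
#'   represented whenever `n >= 4`).
#' @param seed RNG seed.
#' @return Data frame: `id`, `title`, `abstract` (first sentence of the
#'   abstract), `gold_1a`, `gold_1b`.
#' @export
generate_title_abstract_fixtures <- function(n, seed = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  pos_titles <- c(
    "A Randomized Controlled Trial of %s",
    "a randomised trial of %s in children",
    "Cluster randomisation of %s: outcomes at one year",
    "RANDOMIZED evaluation of %s",
    "Effect of %s on recovery: randomization to two arms")
  neg_titles <- c(
    "An observational cohort study of %s",
    "A qualitative interview study of %s",
    "Prevalence of %s in primary care",
    "Case series: %s in elderly patients")
  pos_abstracts <- c(
    "Background: We conducted a trial of %s.",
    "OBJECTIVE. To assess %s in adults.",
    "METHODS: Participants received %s for six weeks.",
    "Main outcome measures: change in %s at followup.",
    "CONCLUSIONS. %s improved outcomes.")
  neg_abstracts <- c(
    "We conducted a trial of %s in two hospitals.",
    "This study examined %s over twelve months.",
    "A total of 120 patients received %s.",
    "Little is known about %s in routine care.")
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      g1a <- c(TRUE, FALSE, TRUE, FALSE)[(i - 1L) %% 4L + 1L]
      g1b <- c(TRUE, TRUE, FALSE, FALSE)[(i - 1L) %% 4L + 1L]
      x <- paste(title_words(2), collapse = " ")
      tpool <- if (g1a) pos_titles else neg_titles
      apool <- if (g1b) pos_abstracts else neg_abstracts
      out[[i]] <- data.frame(
        id = sprintf("fix%03d", i),
        title = sprintf(tpool[sample.int(length(tpool), 1)], x),
        abstract = sprintf(apool[sample.int(length(apool), 1)], x),
        gold_1a = g1a, gold_1b = g1b, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
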