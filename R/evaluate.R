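# Evaluation protocol: grouped k-fold cross-validation, sentence-level
# micro/macro precision/recall/F1 and AUC, article-level ANY and 1+
# schemes, and McNemar matched-pairs comparison of two classifiers.

#' Grouped k-fold plan over articles
#'
#' Articles (the groups) are shuffled under `seed` and dealt round-robin
#' into `k` folds, so all sentences of an article share a fold and no
#' article contributes to both training and test data.
#'
#' @param article_ids Character vector of article ids (a `consort_corpus`
#'   is also accepted).
#' @param k Number of folds (default 5).
#' @param seed Shuffling seed.
#' @return A list of class `consort_folds`: `k`, `seed`, and `assignment`
#'   (named integer vector, article id -> fold in `1:k`).
#' @export
group_kfold <- function(article_ids, k = 5L, seed = 1L) {
  if (is.data.frame(article_ids)) article_ids <- article_ids$article_id
  ids <- unique(as.character(article_ids))
  if (k < 2L) stopf("k must be >= 2")
  if (length(ids) < k) {
    stopf("cannot make %d folds from %d articles", k, length(ids))
  }
  shuffled <- with_seed(seed, sample(ids))
  assignment <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignment = assignment),
            class = "consort_folds")
}

#' @export
print.consort_folds <- function(x, ...) {
  cat(sprintf("Grouped %d-fold plan over %d articles (seed %d); fold sizes: %s\n",
              x$k, length(x$assignment), x$seed,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

# Align gold corpus rows with prediction rows on (article_id, sentence_index).
align_units <- function(gold, predictions) {
  key_g <- paste(gold$article_id, gold$sentence_index, sep = "\r")
  key_p <- paste(predictions$article_id, predictions$sentence_index, sep = "\r")
  m <- match(key_g, key_p)
  if (anyNA(m) || length(key_g) != length(key_p)) {
    stopf("gold and predictions are not aligned on (article_id, sentence_index)")
  }
  m
}

# Binary decision matrix [units x labels] from "|"-joined label strings.
decision_matrix <- function(labels, label_set) {
  label_matrix(labels, label_set) > 0
}

per_label_prf <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(precision = precision, recall = recall, f1 = f1)
}

# Mann-Whitney / rank identity for ROC AUC on pooled scores.
rank_auc <- function(scores, truth) {
  pos <- sum(truth); neg <- sum(!truth)
  if (pos == 0 || neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - pos * (pos + 1) / 2) / (pos * neg)
}

make_eval_report <- function(codes, tp, fp, fn, tn = NULL, auc = NA_real_,
                             level = "sentence", n_units = NA_integer_) {
  prf <- per_label_prf(tp, fp, fn)
  per_label <- data.frame(code = codes, tp = tp, fp = fp, fn = fn,
                          stringsAsFactors = FALSE)
  if (!is.null(tn)) per_label$tn <- tn
  per_label$precision <- prf$precision
  per_label$recall <- prf$recall
  per_label$f1 <- prf$f1
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  micro_p <- if (TP + FP > 0) TP / (TP + FP) else 0
  micro_r <- if (TP + FN > 0) TP / (TP + FN) else 0
  micro_f1 <- if (micro_p + micro_r > 0)
    2 * micro_p * micro_r / (micro_p + micro_r) else 0
  # Labels absent from both gold and predictions have undefined F1 and are
  # excluded from the macro average (rare items may vanish from small folds).
  active <- (tp + fp + fn) > 0
  macro_f1 <- if (any(active)) mean(prf$f1[active]) else NA_real_
  structure(list(
    level = level, per_label = per_label,
    micro = c(precision = micro_p, recall = micro_r, f1 = micro_f1),
    macro_f1 = macro_f1, auc = auc, n_units = n_units
  ), class = "consort_eval")
}

#' @export
print.consort_eval <- function(x, ...) {
  cat(sprintf("%s-level evaluation over %s units\n",
              tools::toTitleCase(x$level), format(x$n_units, big.mark = ",")))
  cat(sprintf("  micro P/R/F1 : %.3f / %.3f / %.3f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  cat(sprintf("  macro F1     : %s\n",
              if (is.na(x$macro_f1)) "NA" else sprintf("%.3f", x$macro_f1)))
  if (!is.na(x$auc)) cat(sprintf("  AUC (micro)  : %.3f\n", x$auc))
  invisible(x)
}

#' Sentence-level evaluation
#'
#' Pools (sentence, label) binary confusions for micro precision, recall
#' and F1; macro-F1 is the unweighted mean of per-label F1 over labels that
#' occur in gold or predictions; AUC (when probability columns are present)
#' is computed over the pooled (sentence, label) scores.
#'
#' @param gold A labelled `consort_corpus`.
#' @param predictions A `consort_predictions` data frame aligned with
#'   `gold` on `(article_id, sentence_index)`.
#' @param label_set Item codes evaluated; defaults to the predictions'
#'   label set.
#' @return A `consort_eval` report.
#' @export
sentence_metrics <- function(gold, predictions, label_set = NULL) {
  label_set <- label_set %||% attr(predictions, "label_set") %||%
    sentence_level_items()$code
  m <- align_units(gold, predictions)
  G <- decision_matrix(gold$labels, label_set)
  P <- decision_matrix(predictions$predicted[m], label_set)
  tp <- colSums(G & P); fp <- colSums(!G & P); fn <- colSums(G & !P)
  pcols <- paste0("p_", label_set)
  auc <- if (all(pcols %in% names(predictions))) {
    S <- as.matrix(as.data.frame(predictions)[m, pcols, drop = FALSE])
    rank_auc(as.numeric(S), as.logical(G))
  } else NA_real_
  make_eval_report(label_set, tp, fp, fn, auc = auc, level = "sentence",
                   n_units = nrow(G) * length(label_set))
}

# Per-(article, item) gold/predicted presence and supporting sentence sets.
article_presence <- function(gold, predictions, label_set) {
  m <- align_units(gold, predictions)
  G <- decision_matrix(gold$labels, label_set)
  P <- decision_matrix(predictions$predicted[m], label_set)
  ids <- gold$article_id
  arts <- unique(ids)
  gold_present <- pred_present <- overlap <-
    matrix(FALSE, length(arts), length(label_set),
           dimnames = list(arts, label_set))
  for (a in arts) {
    rows <- ids == a
    gold_present[a, ] <- colSums(G[rows, , drop = FALSE]) > 0
    pred_present[a, ] <- colSums(P[rows, , drop = FALSE]) > 0
    overlap[a, ] <- colSums(G[rows, , drop = FALSE] &
                            P[rows, , drop = FALSE]) > 0
  }
  list(gold = gold_present, pred = pred_present, overlap = overlap)
}

#' Article-level evaluation, ANY scheme
#'
#' For each (article, item) pair: the item is gold-present if at least one
#' gold sentence carries it, predicted-present if at least one sentence is
#' predicted for it. The confusion is over article-by-item units. This is
#' the lenient scheme: any supporting sentence, correct or not, counts.
#'
#' @inheritParams sentence_metrics
#' @return A `consort_eval` report (per-label counts include `tn`).
#' @export
article_any <- function(gold, predictions, label_set = NULL) {
  label_set <- label_set %||% attr(predictions, "label_set") %||%
    sentence_level_items()$code
  pr <- article_presence(gold, predictions, label_set)
  tp <- colSums(pr$gold & pr$pred)
  fp <- colSums(!pr$gold & pr$pred)
  fn <- colSums(pr$gold & !pr$pred)
  tn <- colSums(!pr$gold & !pr$pred)
  make_eval_report(label_set, tp, fp, fn, tn = tn, level = "article (ANY)",
                   n_units = nrow(pr$gold) * length(label_set))
}

#' Article-level evaluation, 1+ scheme
#'
#' As [article_any()], but a unit counts as a true positive only when the
#' predicted and gold supporting-sentence sets for the item intersect. A
#' unit where both sides are present but with zero sentence overlap is
#' counted as one false positive and one false negative (the prediction
#' points at the wrong sentences and the true evidence is missed).
#'
#' @inheritParams sentence_metrics
#' @return A `consort_eval` report.
#' @export
article_one_plus <- function(gold, predictions, label_set = NULL) {
  label_set <- label_set %||% attr(predictions, "label_set") %||%
    sentence_level_items()$code
  pr <- article_presence(gold, predictions, label_set)
  both_no_overlap <- pr$gold & pr$pred & !pr$overlap
  tp <- colSums(pr$gold & pr$pred & pr$overlap)
  fp <- colSums(!pr$gold & pr$pred) + colSums(both_no_overlap)
  fn <- colSums(pr$gold & !pr$pred) + colSums(both_no_overlap)
  tn <- colSums(!pr$gold & !pr$pred)
  make_eval_report(label_set, tp, fp, fn, tn = tn, level = "article (1+)",
                   n_units = nrow(pr$gold) * length(label_set))
}

#' McNemar matched-pairs comparison of two classifiers
#'
#' Compares two systems on identical (sentence, label) binary decisions.
#' With `n01` the units system A got right and B wrong and `n10` the
#' converse, the continuity-corrected statistic
#' `(|n01 - n10| - 1)^2 / (n01 + n10)` is referred to the chi-square
#' distribution with 1 df; when `n01 + n10 < 20` the exact two-sided
#' binomial test is used instead; `p = 1` when there are no discordant
#' units.
#'
#' @param predictions_a,predictions_b `consort_predictions` for the two
#'   systems, aligned with `gold`.
#' @param gold A labelled `consort_corpus`.
#' @param label_set Item codes over which decisions are pooled.
#' @return A list of class `consort_mcnemar`: `statistic` (NA on the exact
#'   branch), `p_value`, `n01`, `n10`, `method`.
#' @export
mcnemar_compare <- function(predictions_a, predictions_b, gold,
                            label_set = NULL) {
  label_set <- label_set %||% attr(predictions_a, "label_set") %||%
    sentence_level_items()$code
  ma <- align_units(gold, predictions_a)
  mb <- align_units(gold, predictions_b)
  G <- decision_matrix(gold$labels, label_set)
  A <- decision_matrix(predictions_a$predicted[ma], label_set)
  B <- decision_matrix(predictions_b$predicted[mb], label_set)
  correct_a <- A == G
  correct_b <- B == G
  mcnemar_counts_test(sum(correct_a & !correct_b),
                      sum(!correct_a & correct_b))
}

#' McNemar test from discordant counts
#'
#' @param n01 Units the first system got right and the second wrong.
#' @param n10 Units the first system got wrong and the second right.
#' @param exact_below Threshold on `n01 + n10` below which the exact
#'   binomial branch is used (default 20).
#' @return A `consort_mcnemar` list (see [mcnemar_compare()]).
#' @export
mcnemar_counts_test <- function(n01, n10, exact_below = 20L) {
  n01 <- as.integer(n01); n10 <- as.integer(n10)
  if (n01 < 0L || n10 < 0L) stopf("counts must be non-negative")
  n <- n01 + n10
  if (n == 0L) {
    out <- list(statistic = NA_real_, p_value = 1, n01 = n01, n10 = n10,
                method = "degenerate (no discordant pairs)")
  } else if (n < exact_below) {
    k <- min(n01, n10)
    p <- min(1, 2 * pbinom(k, n, 0.5))
    out <- list(statistic = NA_real_, p_value = p, n01 = n01, n10 = n10,
                method = "exact binomial")
  } else {
    # continuity correction clamped at zero (equal discordant counts)
    stat <- max(abs(n01 - n10) - 1, 0)^2 / n
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    out <- list(statistic = stat, p_value = p, n01 = n01, n10 = n10,
                method = "continuity-corrected chi-square")
  }
  class(out) <- "consort_mcnemar"
  out
}

#' @export
print.consort_mcnemar <- function(x, ...) {
  cat(sprintf("McNemar matched-pairs test (%s)\n", x$method))
  cat(sprintf("  discordant: n01 = %d, n10 = %d\n", x$n01, x$n10))
  if (!is.na(x$statistic)) cat(sprintf("  statistic : %.4f\n", x$statistic))
  cat(sprintf("  p-value   : %.4g\n", x$p_value))
  invisible(x)
}

#' Grouped cross-validation of the sentence classifier
#'
#' For each fold: fits the model on the remaining folds (plus any
#' augmentation instances whose source article lies in those folds),
#' predicts the held-out fold, and evaluates at the sentence level and the
#' article (ANY) and article (1+) levels. Folds are aggregated as the
#' unweighted mean and standard deviation over folds.
#'
#' @param corpus A labelled `consort_corpus`.
#' @param config A [consort_config()].
#' @param plan A [group_kfold()] plan (defaults to a 5-fold plan seeded from
#'   `config$seed`).
#' @param augmented Optional `consort_augmentation` data frame. Instances
#'   with a non-missing `source_article_id` join only the training folds
#'   containing that article; instances without one (generative) join every
#'   training fold. Augmented instances never enter a test fold.
#' @param schemes Evaluation schemes to compute.
#' @return A list of class `consort_cv`: `folds` (per-fold reports),
#'   `summary` (data frame of mean and sd per scheme and metric), `plan`.
#' @export
cross_validate <- function(corpus, config = consort_config(), plan = NULL,
                           augmented = NULL,
                           schemes = c("sentence", "article_any",
                                       "article_one_plus")) {
  validate_corpus(corpus)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(plan)) plan <- group_kfold(corpus, k = 5L, seed = config$seed)
  assignment <- plan$assignment
  missing_ids <- setdiff(unique(corpus$article_id), names(assignment))
  if (length(missing_ids)) {
    stopf("fold plan does not cover article(s): %s",
          paste(head(missing_ids, 3), collapse = ", "))
  }
  fold_of <- assignment[corpus$article_id]
  fold_reports <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    test_rows <- fold_of == f
    if (!any(test_rows)) stopf("fold %d has no test sentences", f)
    train <- new_corpus(corpus[!test_rows, , drop = FALSE])
    test <- new_corpus(corpus[test_rows, , drop = FALSE])
    aug_f <- NULL
    if (!is.null(augmented) && nrow(augmented)) {
      src <- augmented$source_article_id
      in_train <- is.na(src) | !(src %in% names(assignment)) |
        assignment[src] != f
      in_train[is.na(in_train)] <- TRUE
      aug_f <- augmented[in_train, , drop = FALSE]
      # instances sourced from the test fold were dropped above; assert it
      stopifnot(!any(!is.na(aug_f$source_article_id) &
                     aug_f$source_article_id %in% unique(test$article_id)))
    }
    model <- consort_fit(train, config, augmented = aug_f)
    preds <- predict(model, test)
    rep_f <- list(fold = f)
    if ("sentence" %in% schemes) {
      rep_f$sentence <- sentence_metrics(test, preds, config$label_set)
    }
    if ("article_any" %in% schemes) {
      rep_f$article_any <- article_any(test, preds, config$label_set)
    }
    if ("article_one_plus" %in% schemes) {
      rep_f$article_one_plus <- article_one_plus(test, preds, config$label_set)
    }
    fold_reports[[f]] <- rep_f
  }
  summary_df <- cv_summary(fold_reports, schemes)
  structure(list(folds = fold_reports, summary = summary_df, plan = plan,
                 config = config),
            class = "consort_cv")
}

cv_summary <- function(fold_reports, schemes) {
  rows <- list()
  for (scheme in schemes) {
    metric_of <- function(rep_f, metric) {
      r <- rep_f[[scheme]]
      switch(metric,
             precision = unname(r$micro["precision"]),
             recall = unname(r$micro["recall"]),
             f1 = unname(r$micro["f1"]),
             macro_f1 = r$macro_f1,
             auc = r$auc)
    }
    for (metric in c("precision", "recall", "f1", "macro_f1", "auc")) {
      vals <- vapply(fold_reports, metric_of, numeric(1), metric = metric)
      if (all(is.na(vals))) next
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, metric = metric,
        mean = mean(vals, na.rm = TRUE), sd = sd(vals, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.consort_cv <- function(x, ...) {
  cat(sprintf("Grouped %d-fold cross-validation (%d articles)\n",
              x$plan$k, length(x$plan$assignment)))
  s <- x$summary
  s$mean <- sprintf("%.3f", s$mean)
  s$sd <- sprintf("(%.3f)", s$sd)
  print(s, row.names = FALSE, right = FALSE)
  invisible(x)
}
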