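test_that("grouped folds partition articles deterministically", {
  ids <- sprintf("a%02d", 1:50)
  plan <- group_kfold(ids, k = 5L, seed = 3L)
  expect_equal(sort(unname(tabulate(plan$assignment, 5L))), rep(10L, 5))
  expect_setequal(names(plan$assignment), ids)
  expect_identical(plan$assignment, group_kfold(ids, 5L, 3L)$assignment)
  expect_false(identical(plan$assignment, group_kfold(ids, 5L, 4L)$assignment))
  expect_error(group_kfold(ids[1:3], k = 5L), "folds")
})

test_that("sentence metrics reproduce the hand-pooled worked example", {
  gold <- data.frame(article_id = "a", sentence_index = 0:2, part = "body",
                     section_path = "", text = c("s1.", "s2.", "s3."),
                     labels = c("4a", "5", ""), stringsAsFactors = FALSE)
  pred <- data.frame(article_id = "a", sentence_index = 0:2,
                     predicted = c("4a", "4a", "5"), stringsAsFactors = FALSE)
  r <- sentence_metrics(gold, pred, label_set = c("4a", "5"))
  expect_equal(unname(r$micro["precision"]), 1 / 3)
  expect_equal(unname(r$micro["recall"]), 1 / 2)
  expect_equal(unname(r$micro["f1"]), 0.4)
  # per-label: F1(4a) = 2/3, F1(5) = 0 -> macro 1/3
  expect_equal(r$per_label$f1[r$per_label$code == "4a"], 2 / 3)
  expect_equal(r$per_label$f1[r$per_label$code == "5"], 0)
  expect_equal(r$macro_f1, 1 / 3)
})

test_that("perfect predictions score 1 across schemes", {
  co <- tiny_corpus()
  pred <- data.frame(article_id = co$article_id,
                     sentence_index = co$sentence_index,
                     predicted = co$labels, stringsAsFactors = FALSE)
  ls <- sentence_level_items()$code
  expect_equal(unname(sentence_metrics(co, pred, ls)$micro["f1"]), 1)
  expect_equal(unname(article_any(co, pred, ls)$micro["f1"]), 1)
  expect_equal(unname(article_one_plus(co, pred, ls)$micro["f1"]), 1)
})

test_that("article (ANY) counts presence at the article-item level", {
  gold <- data.frame(
    article_id = c("A", "A", "B", "B"), sentence_index = c(0:1, 0:1),
    part = "body", section_path = "",
    text = paste0("s", 1:4, "."),
    labels = c("4a", "", "6a", ""), stringsAsFactors = FALSE)
  pred <- data.frame(article_id = gold$article_id,
                     sentence_index = gold$sentence_index,
                     predicted = c("4a", "6a", "", ""),
                     stringsAsFactors = FALSE)
  r <- article_any(gold, pred, label_set = c("4a", "6a"))
  expect_equal(sum(r$per_label$tp), 1)
  expect_equal(sum(r$per_label$fp), 1)
  expect_equal(sum(r$per_label$fn), 1)
  expect_equal(sum(r$per_label$tn), 1)
  expect_equal(unname(r$micro["f1"]), 0.5)
  # an extra sentence-level FP on an already-present item costs nothing
  pred2 <- pred
  pred2$predicted <- c("4a", "4a", "6a", "")
  r2 <- article_any(gold, pred2, label_set = c("4a", "6a"))
  expect_equal(sum(r2$per_label$fp), 0)
  expect_equal(unname(r2$micro["f1"]), 1)
})

test_that("article (1+) requires supporting-sentence overlap", {
  gold <- data.frame(
    article_id = "A", sentence_index = 0:3, part = "body", section_path = "",
    text = paste0("s", 1:4, "."),
    labels = c("4a", "4a", "", ""), stringsAsFactors = FALSE)
  hit <- data.frame(article_id = "A", sentence_index = 0:3,
                    predicted = c("", "4a", "", "4a"), stringsAsFactors = FALSE)
  r_hit <- article_one_plus(gold, hit, label_set = "4a")
  expect_equal(r_hit$per_label$tp, 1)
  miss <- data.frame(article_id = "A", sentence_index = 0:3,
                     predicted = c("", "", "", "4a"), stringsAsFactors = FALSE)
  r_miss <- article_one_plus(gold, miss, label_set = "4a")
  expect_equal(r_miss$per_label$tp, 0)
  expect_equal(r_miss$per_label$fp, 1)
  expect_equal(r_miss$per_label$fn, 1)
  r_any <- article_any(gold, miss, label_set = "4a")
  expect_equal(r_any$per_label$tp, 1)
})

test_that("metrics match the brute-force enumerator on random cases", {
  set.seed(99)
  for (k in 1:200) {
    case <- random_eval_case()
    got_s <- sentence_metrics(case$gold, case$pred, case$label_set)
    got_a <- article_any(case$gold, case$pred, case$label_set)
    got_o <- article_one_plus(case$gold, case$pred, case$label_set)
    want <- brute_force_metrics(case$gold, case$pred, case$label_set)
    expect_equal(unname(got_s$micro), want$micro)
    expect_equal(got_s$macro_f1, want$macro_f1)
    expect_equal(unname(got_a$micro), want$any)
    expect_equal(unname(got_o$micro), want$one_plus)
    # 1+ is never more lenient than ANY
    expect_lte(got_o$micro["f1"], got_a$micro["f1"] + 1e-12)
  }
})

test_that("macro-F1 is invariant under label permutation", {
  set.seed(7)
  case <- random_eval_case()
  r1 <- sentence_metrics(case$gold, case$pred, case$label_set)
  r2 <- sentence_metrics(case$gold, case$pred, rev(case$label_set))
  expect_equal(r1$macro_f1, r2$macro_f1)
  expect_equal(unname(r1$micro), unname(r2$micro))
})

test_that("McNemar branches follow the discordant-count rules", {
  r <- mcnemar_counts_test(15, 5)
  expect_equal(r$statistic, (abs(15 - 5) - 1)^2 / 20)
  expect_equal(r$statistic, 4.05)
  expect_equal(r$p_value, pchisq(4.05, 1, lower.tail = FALSE))
  expect_equal(r$p_value, 0.0442, tolerance = 1e-2)

  rb <- mcnemar_counts_test(3, 1)
  expect_true(is.na(rb$statistic))
  expect_equal(rb$p_value, 0.625)  # 2 * P(X <= 1 | n = 4, p = .5)

  r0 <- mcnemar_counts_test(0, 0)
  expect_equal(r0$p_value, 1)
})

test_that("the chi-square branch matches stats::mcnemar.test", {
  set.seed(13)
  for (k in 1:100) {
    n01 <- sample(5:60, 1); n10 <- sample(5:60, 1)
    if (n01 + n10 < 20) next
    got <- mcnemar_counts_test(n01, n10)
    ref <- stats::mcnemar.test(matrix(c(5, n01, n10, 5), 2), correct = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("mcnemar_compare pools (sentence,label) decisions", {
  co <- tiny_corpus()
  perfect <- data.frame(article_id = co$article_id,
                        sentence_index = co$sentence_index,
                        predicted = co$labels, stringsAsFactors = FALSE)
  r_same <- mcnemar_compare(perfect, perfect, co)
  expect_equal(r_same$n01 + r_same$n10, 0)
  expect_equal(r_same$p_value, 1)
  worse <- perfect
  worse$predicted[co$labels == "4a"] <- ""
  r <- mcnemar_compare(perfect, worse, co)
  expect_equal(r$n01, 2)  # the two 4a sentences
  expect_equal(r$n10, 0)
})

test_that("cross-validation reports per-fold rows and excludes test-fold augmentation", {
  co <- small_cued_corpus(6L, seed = 55L)
  cfg <- fast_config()
  plan <- group_kfold(co, k = 3L, seed = 2L)
  # augmentation instances traceable to each article
  aug <- do.call(rbind, lapply(unique(co$article_id), function(a) {
    data.frame(method = "eda", source_article_id = a,
               source_id = paste0(a, ":0"), preceding = "p",
               target = paste("augmented text for", a), trailing = "t",
               label = "6b", section_path = "Methods",
               stringsAsFactors = FALSE)
  }))
  cv <- cross_validate(co, cfg, plan, augmented = aug, schemes = "sentence")
  expect_length(cv$folds, 3L)
  f1s <- vapply(cv$folds, function(f) unname(f$sentence$micro["f1"]),
                numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "f1"], mean(f1s))
  expect_equal(cv$summary$sd[cv$summary$metric == "f1"], sd(f1s))
})

test_that("no article contributes sentences to both train and test", {
  co <- small_cued_corpus(6L, seed = 56L)
  plan <- group_kfold(co, k = 3L, seed = 2L)
  fold_of <- plan$assignment[co$article_id]
  for (f in 1:3) {
    train_articles <- unique(co$article_id[fold_of != f])
    test_articles <- unique(co$article_id[fold_of == f])
    expect_length(intersect(train_articles, test_articles), 0)
  }
})

test_that("pooled AUC agrees with an independent ROC implementation", {
  co <- small_cued_corpus(2L, seed = 61L)
  m <- consort_fit(co, fast_config())
  p <- predict(m, co)
  r <- sentence_metrics(co, p)
  ls <- attr(p, "label_set")
  G <- sapply(ls, function(l)
    grepl(paste0("(^|\\|)", l, "($|\\|)"), co$labels))
  S <- as.matrix(as.data.frame(p)[, paste0("p_", ls)])
  ref <- suppressMessages(pROC::auc(as.vector(G), as.vector(S),
                                    direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
})
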