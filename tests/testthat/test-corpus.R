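test_that("corpus CSV round-trips all sentence fields", {
  co <- tiny_corpus()
  path <- tempfile(fileext = ".csv")
  write_corpus(co, path)
  back <- read_corpus(path)
  expect_equal(as.data.frame(back), as.data.frame(co))

  jl <- tempfile(fileext = ".jsonl")
  write_corpus(co, jl, format = "jsonl")
  back2 <- read_corpus(jl, format = "jsonl")
  expect_equal(as.data.frame(back2), as.data.frame(co))
})

test_that("multi-label cells and unknown codes are handled at parse time", {
  co <- tiny_corpus()
  co$labels[3] <- "6a|11a"
  path <- tempfile(fileext = ".csv")
  write_corpus(co, path)
  back <- read_corpus(path)
  expect_setequal(strsplit(back$labels[back$labels == "6a|11a"], "\\|")[[1]],
                  c("6a", "11a"))

  bad <- tiny_corpus()
  bad$labels[4] <- "99z"
  path2 <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(bad), path2, row.names = FALSE)
  expect_error(read_corpus(path2), "99z")
})

test_that("missing required columns are named in the parse error", {
  co <- as.data.frame(tiny_corpus())
  co$labels <- NULL
  path <- tempfile(fileext = ".csv")
  write.csv(co, path, row.names = FALSE)
  expect_error(read_corpus(path), "labels")
})

test_that("corpus statistics match hand counts and are additive", {
  co <- tiny_corpus()
  st <- corpus_stats(co)
  expect_equal(st$n_articles, 2L)
  expect_equal(st$n_sentences, 11L)
  expect_equal(st$n_labeled_sentences, 7L)
  expect_equal(st$n_label_instances, 7L)
  expect_equal(st$mean_items_per_article, 3.5)

  # hand-constructed single-article case: labels {a},{a,b},{}
  one <- data.frame(article_id = "x", sentence_index = 0:2, part = "body",
                    section_path = "Methods",
                    text = c("s one.", "s two.", "s three."),
                    labels = c("4a", "4a|5", ""), stringsAsFactors = FALSE)
  st1 <- corpus_stats(one)
  expect_equal(st1$n_labeled_sentences, 2L)
  expect_equal(st1$n_label_instances, 3L)
  expect_equal(st1$mean_items_per_article, 2)

  # additivity: stats of a concatenation combine field-wise
  both <- rbind(as.data.frame(co), one)
  stb <- corpus_stats(both)
  expect_equal(stb$n_sentences, st$n_sentences + st1$n_sentences)
  expect_equal(stb$n_labeled_sentences,
               st$n_labeled_sentences + st1$n_labeled_sentences)
  expect_equal(stb$n_label_instances,
               st$n_label_instances + st1$n_label_instances)
  expect_equal(stb$mean_items_per_article,
               (2 * st$mean_items_per_article + st1$mean_items_per_article) / 3)
  expect_equal(corpus_stats(co[0, ])$n_sentences, 0L)
})

test_that("prediction files round-trip with full probability precision", {
  co <- small_cued_corpus(2L)
  m <- consort_fit(co, fast_config())
  preds <- predict(m, co)
  path <- tempfile(fileext = ".jsonl")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(back$predicted, preds$predicted)
  pcols <- paste0("p_", attr(preds, "label_set"))
  expect_equal(as.matrix(as.data.frame(back)[, pcols]),
               as.matrix(as.data.frame(preds)[, pcols]),
               tolerance = 1e-9, ignore_attr = TRUE)

  empty <- preds[0, ]
  attr(empty, "label_set") <- attr(preds, "label_set")
  path2 <- tempfile(fileext = ".jsonl")
  write_predictions(empty, path2)
  expect_equal(nrow(read_predictions(path2)), 0L)
  header <- jsonlite::fromJSON(readLines(path2)[1])
  expect_equal(header$label_set, attr(preds, "label_set"))
})

test_that("JATS XML ingestion builds nested section paths", {
  p2 <- write_jats_fixture(tempfile(fileext = ".xml"), levels = 2L)
  art <- read_jats_xml(p2)
  expect_true(any(art$section_path == "Methods>Patients"))
  expect_equal(art$text[art$part == "title"], "A randomized trial of X")
  expect_true(sum(art$part == "abstract") >= 2)
  expect_equal(art$sentence_index, seq_len(nrow(art)) - 1L)

  p3 <- write_jats_fixture(tempfile(fileext = ".xml"), levels = 3L)
  art3 <- read_jats_xml(p3)
  expect_true(any(art3$section_path == "Methods>Patients>Subgroup"))
  expect_equal(max(lengths(strsplit(art3$section_path, ">"))), 3L)

  p0 <- write_jats_fixture(tempfile(fileext = ".xml"), with_abstract = FALSE)
  expect_equal(sum(read_jats_xml(p0)$part == "abstract"), 0L)

  bad <- tempfile(fileext = ".xml")
  writeLines("<article><unclosed>", bad)
  expect_error(read_jats_xml(bad), "malformed XML")
})
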