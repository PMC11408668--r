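test_that("the model memorizes a small fully-cued training set", {
  co <- small_cued_corpus(2L, seed = 11L)
  m <- consort_fit(co, consort_config(seed = 5L, encoder_dim = 512L))
  sm <- sentence_metrics(co, predict(m, co))
  expect_equal(unname(sm$micro["f1"]), 1.0)
})

test_that("training is reproducible and prediction deterministic", {
  co <- small_cued_corpus(2L, seed = 12L)
  cfg <- fast_config()
  m1 <- consort_fit(co, cfg)
  m2 <- consort_fit(co, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  p1 <- predict(m1, co)
  p2 <- predict(m1, co)
  expect_identical(p1, p2)
})

test_that("duplicate sentences receive identical probability vectors", {
  co <- small_cued_corpus(2L, seed = 13L)
  m <- consort_fit(co, fast_config())
  dup <- co[co$part == "body", ][1:2, ]
  dup$article_id <- c("z1", "z2")
  dup$sentence_index <- c(0L, 0L)
  dup$text <- "participants received treatment weekly."
  dup$section_path <- "Methods"
  dup$labels <- ""
  class(dup) <- c("consort_corpus", "data.frame")
  p <- predict(m, dup)
  pcols <- grep("^p_", names(p), value = TRUE)
  expect_equal(unlist(p[1, pcols]), unlist(p[2, pcols]))
})

test_that("prediction is invariant to article order", {
  co <- small_cued_corpus(3L, seed = 14L)
  m <- consort_fit(co, fast_config())
  p_fwd <- predict(m, co)
  rev_co <- co[order(co$article_id, decreasing = TRUE), ]
  class(rev_co) <- c("consort_corpus", "data.frame")
  p_rev <- predict(m, rev_co)
  key <- function(p) paste(p$article_id, p$sentence_index)
  p_rev <- p_rev[match(key(p_fwd), key(p_rev)), ]
  expect_equal(p_fwd$predicted, p_rev$predicted)
})

test_that("probabilities live in [0,1] and respect the threshold contract", {
  co <- small_cued_corpus(2L, seed = 15L)
  m <- consort_fit(co, fast_config())
  p <- predict(m, co)
  pcols <- grep("^p_", names(p), value = TRUE)
  P <- as.matrix(as.data.frame(p)[, pcols])
  expect_true(all(P >= 0 & P <= 1))
  # predicted sets are exactly the >= threshold labels
  labs <- attr(p, "label_set")
  for (i in sample(nrow(p), 10)) {
    expect_setequal(strsplit(p$predicted[i], "\\|")[[1]],
                    labs[P[i, ] >= attr(p, "threshold")])
  }
})

test_that("binarize uses >= and is monotone in the threshold", {
  expect_setequal(binarize(c(a = 0.9, b = 0.2, c = 0.7), 0.5), c("a", "c"))
  expect_setequal(binarize(c(a = 0.5), 0.5), "a")
  expect_length(binarize(c(a = 0, b = 0), 0.5), 0)
  set.seed(42)
  for (k in 1:50) {
    pr <- setNames(runif(6), letters[1:6])
    t1 <- runif(1, 0.05, 0.95)
    t2 <- runif(1, 0.05, t1)
    expect_true(all(binarize(pr, t1) %in% binarize(pr, t2)))
  }
  expect_error(binarize(c(a = 0.5), 0), "threshold")
})

test_that("save/load round trip yields identical predictions", {
  co <- small_cued_corpus(2L, seed = 16L)
  m <- consort_fit(co, fast_config())
  dir <- tempfile()
  save_model(m, dir)
  m2 <- load_model(dir)
  p1 <- predict(m, co)
  p2 <- predict(m2, co)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("training rejects labels outside the configured label set", {
  co <- tiny_corpus()
  cfg <- fast_config(label_set = c("4a", "5"))
  expect_error(consort_fit(co, cfg), "outside config\\$label_set")
  expect_error(consort_fit(co[0, ], fast_config()), "empty")
})

test_that("section-specific models restrict sentences and labels", {
  co <- small_cued_corpus(4L, seed = 17L)
  m <- fit_section_model(co, "Methods", fast_config())
  expect_setequal(m$label_set, items_for_section_group("Methods")$code)
  expect_false("17a" %in% m$label_set)
  expect_error(fit_section_model(co, "Introduction"), "Introduction")
})

test_that("in-context prompts are deterministic with ordered parts", {
  co <- tiny_corpus()
  art <- co[co$article_id == "a1", ]
  items <- sentence_level_items()[1:3, ]
  p0 <- build_icl_prompt(art, items, shots = 0L)
  expect_false(grepl("Examples:", p0))
  expect_true(grepl("Checklist items:", p0))
  expect_true(grepl("Article:", p0))
  # order: task < items < article
  expect_true(regexpr("Checklist items:", p0) < regexpr("Article:", p0))
  pool <- data.frame(text = paste("example", 1:6),
                     labels = c("4a", "", "5", "6a", "4a|5", ""),
                     stringsAsFactors = FALSE)
  p5 <- build_icl_prompt(art, items, shots = 5L, shot_pool = pool)
  expect_equal(lengths(regmatches(p5, gregexpr("Sentence: example", p5))), 5L)
  expect_identical(p5, build_icl_prompt(art, items, shots = 5L, shot_pool = pool))
  expect_error(build_icl_prompt(art, items, shots = 5L, shot_pool = pool[1:3, ]),
               "pool")
})

test_that("generative sequences follow the template and invert cleanly", {
  s <- format_generative_sequence("Methods Patients Adults were eligible", "4a")
  expect_identical(s,
    "Methods Patients Adults were eligible. This sentence describes 4a")
  expect_error(format_generative_sequence("x", ""), "label")
  back <- parse_generative_sequence(s)
  expect_equal(back$label, "4a")
  expect_equal(back$sentence, "Methods Patients Adults were eligible")
})
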