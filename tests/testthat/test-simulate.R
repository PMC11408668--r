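test_that("generation is reproducible under the seed", {
  sp <- generator_spec(n_articles = 3L, sentences_per_article = c(20L, 30L),
                       seed = 5L)
  c1 <- generate_corpus(sp)
  c2 <- generate_corpus(sp)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_corpus(generator_spec(n_articles = 3L,
                                       sentences_per_article = c(20L, 30L),
                                       seed = 6L))
  expect_false(identical(c1$text, c3$text))
})

test_that("generated corpora have the documented structure", {
  co <- generate_corpus(generator_spec(n_articles = 4L,
                                       sentences_per_article = c(30L, 40L),
                                       seed = 8L))
  expect_s3_class(co, "consort_corpus")
  expect_equal(length(unique(co$article_id)), 4L)
  # single 0-based index stream per article
  for (a in split(co, co$article_id)) {
    expect_equal(sort(a$sentence_index), seq_len(nrow(a)) - 1L)
    expect_equal(sum(a$part == "title"), 1L)
    expect_gte(sum(a$part == "abstract"), 4L)
  }
  # nested Methods subsections appear
  expect_true(any(grepl("^Methods>", co$section_path)))
  # labels only on body sentences and all within the sentence-level set
  labs <- co$labels[nzchar(co$labels)]
  expect_true(all(co$part[nzchar(co$labels)] == "body"))
  expect_true(all(unlist(strsplit(labs, "\\|")) %in%
                  sentence_level_items()$code))
  # labelled sentences carry their cue token when cue_strength = 1
  co1 <- generate_corpus(generator_spec(n_articles = 2L,
                                        sentences_per_article = c(20L, 25L),
                                        cue_strength = 1, seed = 9L))
  lab_rows <- which(nzchar(co1$labels))
  ok <- vapply(lab_rows, function(i) {
    all(vapply(strsplit(co1$labels[i], "\\|")[[1]], function(code)
      grepl(paste0("itemcue", code), tolower(co1$text[i])), logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("realized label frequencies track the configured binomial rates", {
  sp <- generator_spec(n_articles = 25L, sentences_per_article = c(180L, 220L),
                       multi_label_rate = 0, seed = 12L)
  co <- generate_corpus(sp)
  expect_gte(nrow(co), 4500L)
  items <- sentence_level_items()
  groups <- vapply(strsplit(co$section_path, ">"), function(p)
    if (length(p)) guess_section_group(p[1]) else NA_character_,
    character(1))
  for (code in c("6a", "17a", "2b", "3b", "21")) {
    grp <- items$section_group[items$code == code]
    eligible <- sum(groups == grp, na.rm = TRUE)
    p <- sp$label_freq[code]
    observed <- sum(grepl(paste0("(^|\\|)", code, "($|\\|)"), co$labels))
    sd_bin <- sqrt(eligible * p * (1 - p))
    expect_lt(abs(observed - eligible * p), 3 * sd_bin + 1)
  }
})

test_that("rare items stay rare and wire into candidate selection", {
  co <- generate_corpus(generator_spec(n_articles = 25L,
                                       sentences_per_article = c(180L, 220L),
                                       seed = 13L))
  for (code in rare_items()) {
    n <- sum(grepl(paste0("(^|\\|)", code, "($|\\|)"), co$labels))
    expect_lt(n, 100L)
  }
  cands <- select_candidates(co)
  expect_true(all(cands$labels %in% rare_items()))
})

test_that("infeasible generator specifications are rejected", {
  expect_error(generator_spec(cue_strength = 1.5), "cue_strength")
  f <- generator_spec()$label_freq
  f["6a"] <- 2
  expect_error(generator_spec(label_freq = f), "\\[0, 1\\]")
  f2 <- generator_spec()$label_freq
  methods_items <- items_for_section_group("Methods")$code
  f2[methods_items] <- 0.3
  expect_error(generator_spec(label_freq = f2), "sum")
})

test_that("title/abstract fixtures are stratified and self-consistent", {
  fx <- generate_title_abstract_fixtures(8L, seed = 3L)
  expect_equal(nrow(fx), 8L)
  expect_equal(sum(fx$gold_1a), 4L)
  expect_equal(sum(fx$gold_1b), 4L)
  stems <- c("random")
  for (i in seq_len(nrow(fx))) {
    has_stem <- grepl("random", tolower(fx$title[i]))
    expect_equal(has_stem, fx$gold_1a[i])
  }
  expect_identical(fx, generate_title_abstract_fixtures(8L, seed = 3L))
})
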