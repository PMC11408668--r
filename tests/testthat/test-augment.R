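test_that("candidate selection keeps single-label rare-item sentences only", {
  co <- tiny_corpus()
  co$labels[co$labels == "4a"] <- "6b"        # rare, single label
  co$labels[co$labels == "5"] <- "6b|11a"     # rare but multi-label
  co$labels[co$labels == "12a"] <- "6a"       # common
  cands <- select_candidates(co)
  expect_true(all(cands$labels == "6b"))
  expect_equal(nrow(cands), 2L)  # both single-label 6b sentences, one per article
  labs <- strsplit(cands$labels, "\\|")
  expect_true(all(lengths(labs) == 1L))
  expect_true(all(unlist(labs) %in% rare_items()))
})

test_that("rate-0 EDA transforms are the identity for all operations", {
  ops <- c("synonym_replacement", "random_insertion", "random_swap",
           "random_deletion")
  set.seed(77)
  vocab <- c("patients", "received", "weekly", "treatment", "outcomes",
             "improved", "baseline", "trial", "randomly", "assigned")
  for (k in 1:125) {
    s <- paste(sample(vocab, sample(3:9, 1), replace = TRUE), collapse = " ")
    for (op in ops) {
      expect_identical(eda_transform(s, op, rate = 0), s)
    }
  }
})

test_that("EDA operations behave per definition on controlled lexicons", {
  syn <- synonym_provider_table(list(big = "large"))
  set.seed(1)
  expect_identical(eda_transform("big trial", "synonym_replacement", 1, syn),
                   "large trial")
  # deletion never empties the sentence
  set.seed(2)
  for (k in 1:50) {
    out <- eda_transform("a b c", "random_deletion", 1)
    expect_true(nchar(out) > 0)
  }
  # empty sentence passes through unchanged
  expect_identical(eda_transform("", "random_swap", 0.5), "")
  # a word is never its own synonym
  p <- synonym_provider_table(list(trial = c("trial", "study")))
  expect_identical(p("trial"), "study")
})

test_that("eda_augment emits exactly n_aug single-label instances", {
  co <- small_cued_corpus(2L, seed = 41L)
  co$labels[co$part == "body"][3] <- "6b"
  cands <- select_candidates(co)
  rec <- cands[1, ]
  aug <- eda_augment(rec, co, seed = 9L)
  expect_equal(nrow(aug), 6L)
  expect_true(all(aug$label == rec$labels))
  expect_true(all(nzchar(aug$target)))
  expect_equal(unique(aug$source_article_id), rec$article_id)
  # context copied from the real neighbours
  w <- build_context_window(co[co$article_id == rec$article_id, ],
                            rec$sentence_index)
  expect_true(all(aug$preceding == w$preceding))
  expect_true(all(aug$trailing == w$trailing))
  # deterministic under the seed
  expect_identical(eda_augment(rec, co, seed = 9L), aug)
})

test_that("rephrase prompts byte-match the template", {
  s <- "Allocation was concealed using sealed envelopes"
  expected <- paste0(
    "You are a scientific researcher writing a research paper for ",
    "randomized clinical trials. Please rephrase the following sentence ",
    "6 times: ", s, ". For the 6 rephrased sentences, also provide an ",
    "example preceding sentence and an example trailing sentence. Vary ",
    "the sentence structure and sentence complexity for each sentence. ",
    "Also, vary the use of introductory prepositional phrases in all ",
    "sentences")
  expect_identical(build_rephrase_prompt(s, 6L), expected)
  expect_identical(build_rephrase_prompt(s, 6L), build_rephrase_prompt(s, 6L))
  expect_error(build_rephrase_prompt("", 6L), "non-empty")
})

test_that("generative prompts byte-match the template with edited descriptions", {
  desc <- "Why the trial ended or was stopped"
  expected <- paste0(
    "You are a scientific researcher writing a research paper for ",
    "randomized clinical trials. From your research paper, please provide ",
    "8 different 1 sentence examples of the following: ", desc,
    ". For each example, also provide an example preceding sentence and ",
    "an example trailing sentence. Vary the sentence structure and ",
    "sentence complexity for each example. Also, vary the use of ",
    "introductory prepositional phrases in all examples")
  expect_identical(build_generative_prompt("14b", 8L), expected)
  p6 <- build_generative_prompt("6b", 6L)
  expect_true(grepl("6 different 1 sentence examples", p6))
  expect_true(grepl("Vary the sentence structure and sentence complexity", p6))
})

test_that("item description editing applies the rewrite rules in order", {
  expect_identical(
    edit_item_description(paste0("Important changes to methods after trial ",
      "commencement (such as eligibility criteria), with reasons")),
    "Important changes to methods after trial commencement, with specifics")
  expect_identical(edit_item_description("How sample size was determined"),
                   "How sample size was determined")
  expect_identical(
    edit_item_description("Methods used, when applicable, with reasons"),
    "Methods used, with specifics")
  expect_identical(
    edit_item_description("When applicable, explanation of any interim analyses and stopping guidelines"),
    "explanation of any interim analyses and stopping guidelines")
})

test_that("augmentation responses parse into labelled triples", {
  txt <- canned_response(4)
  inst <- parse_augmentation_response(txt, "9", method = "llm_generative")
  expect_equal(nrow(inst), 4L)
  expect_true(all(inst$label == "9"))
  expect_true(all(nzchar(inst$preceding) & nzchar(inst$trailing)))
  expect_equal(inst$section_path[1], "Methods")  # canonical group header

  expect_warning(out <- parse_augmentation_response("", "9", "llm_generative"),
                 "empty")
  expect_equal(nrow(out), 0L)

  broken <- paste0(canned_response(2), "\n\n3. Preceding: only a preceding line.")
  expect_warning(inst2 <- parse_augmentation_response(broken, "21", "llm_rephrase"),
                 "malformed")
  expect_equal(nrow(inst2), 2L)
})

test_that("generative accumulation iterates the provider to the target", {
  calls <- 0L
  provider <- function(prompt) {
    calls <<- calls + 1L
    canned_response(8)
  }
  out <- accumulate_generative(provider, "6b", batch_n = 8L, target_total = 100L)
  expect_gte(nrow(out), 100L)
  expect_equal(attr(out, "calls"), 13L)
  expect_equal(calls, 13L)

  dud <- function(prompt) ""
  w <- capture_warnings(out0 <- accumulate_generative(dud, "6b", max_iter = 3L))
  expect_true(any(grepl("cap reached", w)))
  expect_equal(nrow(out0), 0L)
})
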