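test_that("MH keyword extraction matches whole phrases, longest first, in occurrence order", {
  rules <- tiny_rules()$keyword_rules
  out <- extract_mh_keywords(
    "known hypertension and chronic kidney insufficiency for years", rules)
  expect_equal(out, c("hypertension", "chronic kidney insufficiency"))
  # longest-match-first: the longer phrase wins over its sub-phrase
  expect_equal(extract_mh_keywords("chronic kidney insufficiency", rules),
               "chronic kidney insufficiency")
  expect_equal(extract_mh_keywords("isolated kidney insufficiency", rules),
               "kidney insufficiency")
  expect_equal(extract_mh_keywords("no rule phrase here", rules),
               character(0))
  expect_equal(extract_mh_keywords("", rules), character(0))
  expect_equal(extract_mh_keywords(NA, rules), character(0))
  # deduplicated, first-occurrence order
  expect_equal(extract_mh_keywords(
    "diabetes mellitus then hypertension then diabetes mellitus", rules),
    c("diabetes mellitus", "hypertension"))
  # no partial-word matches
  expect_equal(extract_mh_keywords("hypertensional something", rules),
               character(0))
})

test_that("longest-first extraction agrees with a brute-force oracle", {
  rules <- tiny_rules()$keyword_rules
  phrases <- rules$phrase[rules$section == "MH"]
  oracle <- function(text) {
    # greedy token-span scan, longest phrase first, masking token indices
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    taken <- rep(FALSE, length(toks))
    hits <- character(0); pos <- integer(0)
    for (p in phrases[order(-nchar(phrases))]) {
      pt <- strsplit(p, " ", fixed = TRUE)[[1]]
      for (s in seq_len(max(0, length(toks) - length(pt) + 1))) {
        span <- s:(s + length(pt) - 1)
        if (!any(taken[span]) && all(toks[span] == pt)) {
          if (!p %in% hits) { hits <- c(hits, p); pos <- c(pos, s) }
          taken[span] <- TRUE
        }
      }
    }
    hits[order(pos)]
  }
  word_pool <- c("chronic", "kidney", "insufficiency", "hypertension",
                 "diabetes", "mellitus", "heart", "failure", "noise", "word")
  withr::with_seed(21, {
    for (i in 1:40) {
      text <- paste(sample(word_pool, 12, replace = TRUE), collapse = " ")
      expect_equal(extract_mh_keywords(text, rules), oracle(text),
                   info = text)
    }
  })
})

test_that("DD and CC combine directly with empty-section identities", {
  expect_equal(combine_cc("pneumonia", "diarrhea"), "pneumonia diarrhea")
  expect_equal(combine_cc("pneumonia", ""), "pneumonia")
  expect_equal(combine_cc("", "vomiting"), "vomiting")
  expect_equal(combine_cc("pneumonia", NA), "pneumonia")
  expect_error(combine_cc("", ""), "empty")
})

test_that("combination filter fires only when trigger and all companions are present", {
  rules <- tiny_rules()$combination_rules
  txt <- paste("hypertension noted with chronic kidney insufficiency",
               "and heart failure on exam")
  out <- apply_combination_filter(txt, rules)
  expect_match(out, "hypertensive heart and chronic kidney disease with heart failure",
               fixed = TRUE)
  expect_false(grepl("\\bhypertension\\b", out))
  expect_false(grepl("chronic kidney insufficiency", out, fixed = TRUE))
  # unrelated text is preserved
  expect_match(out, "noted with")
  expect_match(out, "on exam")
  # replacement sits at the trigger position
  expect_match(out, "^hypertensive heart")
  # trigger alone: unchanged
  expect_equal(apply_combination_filter("hypertension alone", rules),
               "hypertension alone")
  # companion present but not all checks satisfied: unchanged
  expect_equal(apply_combination_filter("hypertension and heart failure maybe",
                                        tiny_rules()$combination_rules[1, ]),
               "hypertension and heart failure maybe")
})

test_that("independent satisfied rules each fire exactly once", {
  rules <- tibble::tibble(
    trigger = c("alpha", "gamma"),
    companions = list(list("beta"), list("delta")),
    combo_code = c("A11.1", "B22.2"),
    replacement = c("alpha beta combined", "gamma delta combined"))
  rules <- rule_tables(combination_rules = rules)$combination_rules
  out <- apply_combination_filter("alpha x beta y gamma z delta", rules)
  expect_equal(stringr::str_count(out, "alpha beta combined"), 1)
  expect_equal(stringr::str_count(out, "gamma delta combined"), 1)
  expect_equal(out, "alpha beta combined x y gamma delta combined z")
})

test_that("external cause removal is an idempotent contraction matching the per-code filter", {
  expect_equal(remove_external_cause_codes(c("N39.0", "V01.0")), "N39.0")
  expect_equal(remove_external_cause_codes(c("W54.0", "X58", "Y98")),
               character(0))
  expect_equal(remove_external_cause_codes("U07.1"), "U07.1")
  withr::with_seed(17, {
    codes <- paste0(sample(LETTERS, 500, TRUE),
                    sprintf("%02d", sample(0:99, 500, TRUE)), ".",
                    sample(0:9, 500, TRUE))
  })
  once <- remove_external_cause_codes(codes)
  expect_identical(remove_external_cause_codes(once), once)
  expect_true(all(once %in% codes))
  expect_identical(once, codes[vapply(codes, function(cd)
    !is_external_cause(cd), logical(1))])
})

test_that("definition pairs clean the text and map codes bijectively", {
  defs <- tiny_rules()$definitions
  pairs <- build_definition_pairs(defs)
  expect_equal(nrow(pairs), 3)
  i <- which(pairs$labels == "N39.0")
  expect_equal(pairs$input_text[i],
               "urinary tract infection site not specified")
  expect_equal(anyDuplicated(unlist(pairs$labels)), 0)
  expect_error(build_definition_pairs(defs[0, ]), "empty")
  clash <- tibble::tibble(code = c("I10", "I10"),
                          definition = c("one thing", "another thing"))
  expect_error(build_definition_pairs(clash), "differing definitions")
})

test_that("CM example pipeline composes the stage transforms in order", {
  rules <- tiny_rules()
  corp <- discharge_corpus(tibble::tibble(
    doc_id = "d1",
    dd = "Pneumonia.",
    mh = "History of hypertension for 12 years.",
    cc = NA_character_,
    gold_cm = list(c("J18.9", "I10", "V01.0")),
    gold_pcs = list(character(0))
  ))
  ex <- build_cm_examples(corp, rules)
  expect_equal(ex$input_text, "pneumonia hypertension")
  expect_setequal(ex$labels[[1]], c("J18.9", "I10"))

  # only DD present: degenerate composition
  corp2 <- discharge_corpus(tibble::tibble(
    doc_id = "d2", dd = "Stage 4 chronic kidney disease!",
    gold_cm = list("N18.4"), gold_pcs = list(character(0))))
  ex2 <- build_cm_examples(corp2, rules)
  expect_equal(ex2$input_text, "stage four chronic kidney disease")

  # a merged text that satisfies a combination rule is rewritten,
  # but the label set is untouched by the text transform
  corp3 <- discharge_corpus(tibble::tibble(
    doc_id = "d3", dd = "Pneumonia.",
    mh = "hypertension with chronic kidney insufficiency and heart failure",
    gold_cm = list(c("J18.9", "I13.0")), gold_pcs = list(character(0))))
  ex3 <- build_cm_examples(corp3, rules)
  expect_match(ex3$input_text,
               "hypertensive heart and chronic kidney disease with heart failure",
               fixed = TRUE)
  expect_setequal(ex3$labels[[1]], c("J18.9", "I13.0"))
})

test_that("CM example text never contains digits and labels match per-code filtering", {
  synth <- small_synth(n_docs = 60)
  ex <- build_cm_examples(synth$corpus, synth$world$rules)
  expect_false(any(grepl("[0-9]", ex$input_text)))
  brute <- purrr::map(synth$corpus$gold_cm,
                      ~ .x[!vapply(.x, is_external_cause, logical(1))])
  expect_equal(purrr::map(ex$labels, sort), purrr::map(brute, sort))
})
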