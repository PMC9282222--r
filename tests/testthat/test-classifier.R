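toy_examples <- function() {
  # two linearly separable classes over disjoint token sets
  tibble::tibble(
    doc_id = sprintf("t%02d", 1:20),
    input_text = rep(c("fever cough pneumonia consolidation",
                       "dysuria frequency urinary infection"), 10),
    labels = rep(list("J18.9", "N39.0"), 10)
  )
}

test_that("training loss decreases monotonically on a separable toy problem", {
  ex <- toy_examples()
  space <- label_space(c("J18.9", "N39.0"), "CM")
  m <- train_classifier(ex, space, train_config(seed = 1, max_epochs = 20))
  expect_true(all(diff(m$loss_trace[1:5]) < 0))
  # memorizes the separable mapping
  pred <- predict_codes(m, ex$input_text[1:2])
  expect_equal(pred, list("J18.9", "N39.0"))
})

test_that("desk backend is bit-reproducible given data, config and seed", {
  ex <- toy_examples()
  space <- label_space(c("J18.9", "N39.0"), "CM")
  cfg <- train_config(seed = 42, max_epochs = 30)
  m1 <- train_classifier(ex, space, cfg)
  m2 <- train_classifier(ex, space, cfg)
  probe <- c("fever cough", "urinary something", "gibberish tokens")
  expect_identical(predict_scores(m1, probe), predict_scores(m2, probe))
  expect_identical(m1$W, m2$W)
})

test_that("prediction contracts: ranges, empty input, row permutation, no NaN", {
  ex <- toy_examples()
  space <- label_space(c("J18.9", "N39.0"), "CM")
  m <- train_classifier(ex, space, train_config(seed = 1, max_epochs = 10))
  s <- predict_scores(m, c("fever", "unseen gibberish zz"))
  expect_true(all(s >= 0 & s <= 1))
  expect_false(anyNA(s))
  expect_equal(ncol(s), length(space))
  expect_equal(dim(predict_scores(m, character(0))), c(0L, 2L))
  texts <- c("fever cough", "dysuria", "fever dysuria")
  expect_identical(predict_scores(m, texts)[c(3, 1, 2), ],
                   predict_scores(m, texts[c(3, 1, 2)]))
})

test_that("thresholding is monotone with exact boundary behaviour", {
  ex <- toy_examples()
  space <- label_space(c("J18.9", "N39.0"), "CM")
  m <- train_classifier(ex, space, train_config(seed = 1, max_epochs = 10))
  texts <- c("fever cough pneumonia", "dysuria frequency", "fever dysuria")
  s <- predict_scores(m, texts)
  # threshold ~0: everything predicted; strict sub-1 scores at 1: nothing
  expect_true(all(lengths(predict_codes(m, texts, threshold = 1e-12)) ==
                    length(space)))
  expect_true(all(lengths(predict_codes(m, texts,
                                        threshold = 1 - 1e-12)) == 0))
  # elementwise oracle at 0.5
  pred <- predict_codes(m, texts, threshold = 0.5)
  oracle <- purrr::map(seq_len(nrow(s)),
                       ~ colnames(s)[s[.x, ] >= 0.5])
  expect_equal(pred, oracle)
  # monotone nesting across thresholds
  for (t1 in c(0.2, 0.5)) {
    p_lo <- predict_codes(m, texts, threshold = t1)
    p_hi <- predict_codes(m, texts, threshold = t1 + 0.3)
    expect_true(all(purrr::map2_lgl(p_hi, p_lo, ~ all(.x %in% .y))))
  }
})

test_that("label outside the space and empty training sets are rejected", {
  space <- label_space("J18.9", "CM")
  bad <- tibble::tibble(doc_id = "x", input_text = "text",
                        labels = list("N39.0"))
  expect_error(train_classifier(bad, space, train_config()),
               "outside label space")
  expect_error(train_classifier(bad[0, ], space, train_config()),
               "no training examples")
})

test_that("definition pretraining memorizes a single pair and records phases", {
  defs <- build_definition_pairs(tibble::tibble(
    code = "N39.0",
    definition = "Urinary tract infection, site not specified."))
  space <- label_space("N39.0", "CM")
  cfg <- train_config(seed = 3, max_epochs = 50)
  pre <- pretrain_on_definitions(defs, space, cfg)
  s <- predict_scores(pre, defs$input_text)
  expect_equal(colnames(s)[which.max(s[1, ])], "N39.0")
  expect_gt(s[1, "N39.0"], 0.5)
  ex <- toy_examples()[1:2, ]
  ex$labels <- list("N39.0", "N39.0")
  m <- train_classifier(ex, space, cfg, init = pre)
  expect_length(m$provenance$phases, 2)
})

test_that("definition warm start recovers validation mentions phrased like definitions", {
  # training corpus never uses definition phrasing; 30% of validation
  # mentions do, so only the warm-started model can score them
  synth <- small_synth(n_docs = 220, seed = 15,
                       frac_definition_phrasing = 0)
  val_cfg <- synthetic_config(n_docs = 70, n_cm_codes = 60, n_pcs_codes = 30,
                              seed = 16, frac_definition_phrasing = 0.3)
  val_corp <- generate_corpus(synth$world, val_cfg)
  rules <- synth$world$rules
  ex_tr <- build_cm_examples(synth$corpus, rules)
  ex_va <- build_cm_examples(val_corp, rules)
  space <- label_space(unique(unlist(c(ex_tr$labels, ex_va$labels))), "CM")
  cfg <- train_config(seed = 5)
  defs <- build_definition_pairs(
    rules$definitions[rules$definitions$code %in% as.character(space), ])
  cold <- train_classifier(ex_tr, space, cfg)
  warm <- train_classifier(ex_tr, space, cfg,
                           init = pretrain_on_definitions(defs, space, cfg))
  recall_of <- function(m) {
    pred <- predict_codes(m, ex_va$input_text)
    micro_recall(confusion_counts(label_matrix(ex_va$labels, space),
                                  label_matrix(pred, space)))
  }
  expect_gte(recall_of(warm), recall_of(cold))
})

test_that("model save/load round trip reproduces predictions bit-exactly", {
  ex <- toy_examples()
  space <- label_space(c("J18.9", "N39.0"), "CM")
  m <- train_classifier(ex, space, train_config(seed = 9, max_epochs = 15))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  m2 <- load_model(tf)
  texts <- c("fever cough", "dysuria frequency")
  expect_identical(predict_scores(m, texts), predict_scores(m2, texts))
})

test_that("contextual backend trains a linear head over a supplied encoder", {
  # toy pooled representation: counts of two marker tokens
  encoder <- function(texts) {
    cbind(feb = stringr::str_count(texts, "fever"),
          ury = stringr::str_count(texts, "dysuria"))
  }
  ex <- toy_examples()
  space <- label_space(c("J18.9", "N39.0"), "CM")
  cfg <- train_config("CONTEXTUAL", learning_rate = 0.5, max_epochs = 60,
                      encoder = encoder, seed = 2)
  m <- train_classifier(ex, space, cfg)
  pred <- predict_codes(m, c("fever fever", "dysuria burning"))
  expect_equal(pred, list("J18.9", "N39.0"))
  expect_error(train_classifier(ex, space, train_config("CONTEXTUAL")),
               "encoder")
  # truncation limits the tokens an encoder sees
  long <- paste(c("fever", rep("pad", 600)), collapse = " ")
  seen <- NULL
  spy <- function(texts) { seen <<- texts; encoder(texts) }
  cfg2 <- train_config("CONTEXTUAL", encoder = spy, max_epochs = 1,
                       max_tokens = 512)
  invisible(train_classifier(ex[1:2, ], space, cfg2))
  expect_true(all(lengths(strsplit(seen, " ")) <= 512))
})

test_that("learning on a synthetic corpus beats the empty predictor", {
  synth <- small_synth(n_docs = 160, seed = 42)
  sp <- split_train_valid(synth$corpus, 0.9, 42)
  ex <- build_cm_examples(sp$train, synth$world$rules)
  exv <- build_cm_examples(sp$valid, synth$world$rules)
  space <- label_space(unique(unlist(c(ex$labels, exv$labels))), "CM")
  m <- train_classifier(ex, space, train_config(seed = 42))
  pred <- predict_codes(m, exv$input_text)
  f1 <- micro_f1(confusion_counts(label_matrix(exv$labels, space),
                                  label_matrix(pred, space)))
  expect_gt(f1, 0)  # the all-empty predictor has F1 = 0
})
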