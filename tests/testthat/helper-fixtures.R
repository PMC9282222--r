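# Small in-code fixtures shared across tests.

tiny_corpus <- function() {
  discharge_corpus(tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    dd = c("Pneumonia, right lower lobe.", "Urinary tract infection.",
           "Stage 4 chronic kidney disease"),
    sm = c(NA, "laparoscopic appendectomy", NA),
    se = c("chest radiograph shows infiltration", NA,
           "renal ultrasound unremarkable"),
    mh = c("known hypertension and chronic kidney insufficiency",
           "diabetes mellitus for 10 years", NA),
    cc = c(NA, "vomiting", NA),
    gold_cm = list(c("J18.9", "I10"), c("N39.0", "E11.9"), "N18.4"),
    gold_pcs = list(character(0), "0DTJ4ZZ", character(0))
  ))
}

tiny_rules <- function() {
  rule_tables(
    keyword_rules = tibble::tibble(
      phrase = c("hypertension", "chronic kidney insufficiency",
                 "kidney insufficiency", "diabetes mellitus",
                 "heart failure", "biopsy", "endoscope"),
      codes = list("I10", "N18.9", "N18.9", "E11.9", "I50.9",
                   "0DB68ZX", "0DJ08ZZ"),
      section = c("MH", "MH", "MH", "MH", "MH", "SE", "SE")
    ),
    combination_rules = tibble::tibble(
      trigger = "hypertension",
      companions = list(list(c("chronic kidney disease",
                               "chronic kidney insufficiency"),
                             "heart failure")),
      combo_code = "I13.0",
      replacement = "hypertensive heart and chronic kidney disease with heart failure"
    ),
    definitions = tibble::tibble(
      code = c("N39.0", "I10", "I13.0"),
      definition = c("Urinary tract infection, site not specified.",
                     "Essential (primary) hypertension",
                     "Hypertensive heart and chronic kidney disease with heart failure")
    )
  )
}

# deterministic small synthetic world/corpus for mid-weight tests
small_synth <- function(n_docs = 120, seed = 11, ...) {
  cfg <- synthetic_config(n_docs = n_docs, n_cm_codes = 60,
                          n_pcs_codes = 30, seed = seed, ...)
  world <- generate_world(cfg)
  list(cfg = cfg, world = world, corpus = generate_corpus(world, cfg))
}
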