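# ICD-10-PCS example construction: section-combination strategies over
# discharge diagnoses (DD), surgical method (SM) and special-examination
# (SE) keywords.

#' The five ICD-10-PCS input-composition strategies
#'
#' `DD_ONLY` and `SM_ONLY` are single-section baselines. `SM_OR_DD`
#' (strategy 1) uses DD only when the case has no SM. `SMSE_OR_DD`
#' (strategy 2) appends SE keywords to SM, falling back to plain DD.
#' `SMSE_OR_DDSE` (strategy 3) appends SE keywords to whichever primary
#' section is used. SE enters only through the keyword extractor, never as
#' full text, to avoid excessive input length.
#'
#' @return Character vector of strategy names.
#' @export
pcs_strategies <- function() {
  c("DD_ONLY", "SM_ONLY", "SM_OR_DD", "SMSE_OR_DD", "SMSE_OR_DDSE")
}

#' Compose the ICD-10-PCS input text for one document
#'
#' Sections are cleaned and number-converted first; the strategy then picks
#' the primary section and whether SE keywords are appended (single-space
#' separated, first-occurrence order). Labels are the gold PCS codes (there
#' is no external-cause concept on the PCS axis).
#'
#' @param doc One corpus row (a one-row tibble or list with the section
#'   fields and `gold_pcs`).
#' @param strategy One of [pcs_strategies()].
#' @param rules A [rule_tables()] bundle (SE keyword rows are used).
#' @param number_convert Rewrite essential numbers as words before digit
#'   removal? Default `TRUE`.
#' @return A one-row training-example tibble (`doc_id`, `input_text`,
#'   `labels`).
#' @export
compose_pcs_input <- function(doc, strategy, rules, number_convert = TRUE) {
  strategy <- match.arg(strategy, pcs_strategies())
  pats <- if (number_convert) rules$number_patterns else
    default_number_patterns()[0, ]
  prep <- function(x) convert_numbers(clean_text(x), pats)
  dd <- prep(doc$dd[[1]]); sm <- prep(doc$sm[[1]]); se <- prep(doc$se[[1]])
  se_kw <- function() paste(extract_se_keywords(se, rules$keyword_rules),
                            collapse = " ")
  has_sm <- nzchar(sm)
  text <- switch(strategy,
    DD_ONLY = dd,
    SM_ONLY = sm,
    SM_OR_DD = if (has_sm) sm else dd,
    SMSE_OR_DD = if (has_sm) paste(sm, se_kw()) else dd,
    SMSE_OR_DDSE = if (has_sm) paste(sm, se_kw()) else paste(dd, se_kw())
  )
  text <- stringr::str_squish(text)
  if (!nzchar(text)) {
    stop("strategy ", strategy, " yields empty input for document ",
         doc$doc_id[[1]], call. = FALSE)
  }
  tibble(doc_id = doc$doc_id[[1]], input_text = text,
         labels = list(doc$gold_pcs[[1]]))
}

#' Build ICD-10-PCS training examples from a corpus
#'
#' Applies [compose_pcs_input()] to every document. With `strict = TRUE`
#' (default) a document for which the strategy yields empty text raises an
#' error; with `strict = FALSE` such documents are kept with empty input
#' text, so a downstream model predicts nothing for them — this keeps
#' validation document sets identical across strategies in ablation runs.
#'
#' @inheritParams compose_pcs_input
#' @param corpus A corpus tibble.
#' @param strict Error on empty compositions? Default `TRUE`.
#' @return A training-example tibble (`doc_id`, `input_text`, `labels`);
#'   `input_text` may be `""` when `strict = FALSE`.
#' @export
build_pcs_examples <- function(corpus, strategy, rules,
                               number_convert = TRUE, strict = TRUE) {
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    tryCatch(
      compose_pcs_input(corpus[i, ], strategy, rules, number_convert),
      error = function(e) {
        if (strict) stop(e)
        tibble(doc_id = corpus$doc_id[i], input_text = "",
               labels = list(corpus$gold_pcs[[i]]))
      })
  })
  dplyr::bind_rows(rows)
}
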