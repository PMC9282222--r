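# ICD-10-CM example construction: medical-history keyword extraction,
# comorbidity merging, combination-code filtering, external-cause label
# removal and definition pairs, composed in the pipeline order
# clean -> convert numbers -> DD+CC -> +MH keywords -> combination filter.

# Match rule phrases in cleaned text: whole phrase at word boundaries,
# longest phrase first, overlaps resolved in favour of the longer phrase.
# Returns matches in order of first occurrence, deduplicated.
match_phrases <- function(text, phrases) {
  text <- paste0(" ", text, " ")
  found <- character(0)
  pos <- integer(0)
  for (p in unique(phrases[order(-nchar(phrases))])) {
    m <- locate_all_bounded(text, p)
    if (nrow(m) == 0) next
    found <- c(found, p)
    pos <- c(pos, m[1, 1])
    # mask matched spans so shorter phrases cannot rematch inside them
    for (i in seq_len(nrow(m))) {
      substr(text, m[i, 1], m[i, 2]) <- strrep("\x01", m[i, 2] - m[i, 1] + 1)
    }
  }
  found[order(pos)]
}

# All word-boundary occurrences of phrase in " text ": start/end of the
# phrase itself (not the flanking spaces).
locate_all_bounded <- function(padded, phrase) {
  m <- stringr::str_locate_all(
    padded, paste0("(?<=[ \x01])", stringr::str_escape(phrase),
                   "(?=[ \x01])"))[[1]]
  m
}

#' Extract medical-history keywords
#'
#' The medical history (MH) narrative is roughly five times the length of
#' the discharge diagnoses, so only curated keyword phrases (chronic
#' diseases such as hypertension or chronic kidney insufficiency that are
#' often absent from DD) are retained from it. Matching is whole-phrase at
#' word boundaries on cleaned text, longest phrase first; results are in
#' first-occurrence order, deduplicated.
#'
#' @param mh Cleaned, number-converted MH text (scalar).
#' @param rules Keyword-rule tibble; only rows with `section == "MH"` are
#'   used.
#' @return Character vector of matched phrases (possibly empty).
#' @export
extract_mh_keywords <- function(mh, rules) {
  extract_section_keywords(mh, rules, "MH")
}

#' Extract special-examination keywords
#'
#' Special examination (SE) reports mix procedure mentions that map to
#' ICD-10-PCS codes (endoscopy, biopsy) with uninformative narrative
#' (radiology readings, electroencephalography traces). Only curated
#' keyword phrases are retained; unmatched narrative is dropped implicitly.
#'
#' @param se Cleaned SE text (scalar).
#' @param rules Keyword-rule tibble; only rows with `section == "SE"` are
#'   used.
#' @return Character vector of matched phrases (possibly empty).
#' @export
extract_se_keywords <- function(se, rules) {
  extract_section_keywords(se, rules, "SE")
}

extract_section_keywords <- function(text, rules, section) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    return(character(0))
  }
  phrases <- rules$phrase[rules$section == section]
  if (length(phrases) == 0) return(character(0))
  match_phrases(text, phrases)
}

#' Combine discharge diagnoses with comorbidity and complication text
#'
#' The comorbidity-and-complication (CC) section is short (mean ~5 words)
#' but decisive when present (nausea, vomiting, diarrhea, pneumonia), so it
#' is concatenated to DD directly rather than keyword-filtered.
#'
#' @param dd,cc Cleaned section texts (scalars; `NA` or `""` for absent).
#' @return Single combined string.
#' @export
combine_cc <- function(dd, cc) {
  dd <- if (is.null(dd) || is.na(dd)) "" else dd
  cc <- if (is.null(cc) || is.na(cc)) "" else cc
  if (!nzchar(dd) && !nzchar(cc)) {
    stop("both DD and CC are empty: no content to combine", call. = FALSE)
  }
  stringr::str_squish(paste(dd, cc))
}

#' Apply the combination-code filter to input text
#'
#' For each rule whose trigger phrase appears and whose every companion
#' check is satisfied (at least one alternative phrase present), the trigger
#' mention(s) and the matched companion mention(s) are removed and the
#' rule's replacement text — the combination code's definition — is inserted
#' at the trigger's position. This keeps the model from predicting two
#' separate codes where coding rules demand one combination code. Rules are
#' applied in table order, each at most once; unrelated text is preserved.
#' The label set is never touched.
#'
#' @param text Cleaned input text (scalar).
#' @param rules Combination-rule tibble.
#' @return Rewritten text.
#' @export
apply_combination_filter <- function(text, rules) {
  if (is.na(text) || !nzchar(text) || nrow(rules) == 0) return(text)
  tokens <- stringr::str_split_1(text, stringr::fixed(" "))
  for (i in seq_len(nrow(rules))) {
    trig_spans <- phrase_token_spans(tokens, rules$trigger[i])
    if (length(trig_spans) == 0) next
    matched_alts <- purrr::map(rules$companions[[i]], function(group) {
      hit <- purrr::keep(group, ~ length(phrase_token_spans(tokens, .x)) > 0)
      if (length(hit) == 0) NULL else hit
    })
    if (any(purrr::map_lgl(matched_alts, is.null))) next
    insert_at <- trig_spans[[1]][1]
    drop <- rep(FALSE, length(tokens))
    for (sp in trig_spans) drop[sp[1]:sp[2]] <- TRUE
    for (alts in matched_alts) {
      for (a in alts) {
        for (sp in phrase_token_spans(tokens, a)) drop[sp[1]:sp[2]] <- TRUE
      }
    }
    repl <- stringr::str_split_1(clean_text(rules$replacement[i]),
                                 stringr::fixed(" "))
    tokens[drop] <- NA_character_
    tokens[insert_at] <- paste(repl, collapse = " ")
    tokens <- tokens[!is.na(tokens)]
  }
  paste(tokens, collapse = " ")
}

# Token index spans (list of c(start, end)) where the phrase's word
# sequence occurs.
phrase_token_spans <- function(tokens, phrase) {
  pt <- stringr::str_split_1(phrase, stringr::fixed(" "))
  k <- length(pt)
  n <- length(tokens)
  if (k > n) return(list())
  starts <- which(tokens == pt[1])
  starts <- starts[starts + k - 1 <= n]
  spans <- list()
  for (s in starts) {
    if (all(tokens[s:(s + k - 1)] == pt, na.rm = FALSE) &&
        !anyNA(tokens[s:(s + k - 1)])) {
      spans[[length(spans) + 1]] <- c(s, s + k - 1)
    }
  }
  spans
}

#' Remove external cause codes from a label set
#'
#' Codes whose 3-character category lies in \code{[V01, Y98]} are removed;
#' all other codes are preserved. Idempotent contraction, applied to gold
#' labels in both training and evaluation splits.
#'
#' @param labels Character vector of normalized CM codes.
#' @return The filtered vector.
#' @export
remove_external_cause_codes <- function(labels) {
  labels[!is_external_cause(labels)]
}

#' Build definition training pairs
#'
#' One training example per definition entry: the cleaned official code
#' definition as input, the code as the single label — e.g. N39.0 with
#' "urinary tract infection site not specified". Used to warm-start the
#' classifier before corpus training, since record phrasing approximates but
#' differs from the official definitions.
#'
#' @param defs Definition tibble (`code`, `definition`).
#' @param axis `"CM"` or `"PCS"`.
#' @return A training-example tibble (`doc_id`, `input_text`, `labels`).
#' @export
build_definition_pairs <- function(defs, axis = "CM") {
  if (nrow(defs) == 0) stop("empty definition table", call. = FALSE)
  codes <- normalize_icd(defs$code, axis)
  cleaned <- clean_text(defs$definition)
  dup <- duplicated(codes)
  if (any(dup)) {
    clash <- vapply(unique(codes[dup]), function(cd) {
      length(unique(cleaned[codes == cd])) > 1
    }, logical(1))
    if (any(clash)) {
      stop("duplicate codes with differing definitions: ",
           paste(unique(codes[dup])[clash], collapse = ", "), call. = FALSE)
    }
  }
  keep <- !dup
  tibble(doc_id = paste0("def_", codes[keep]),
         input_text = cleaned[keep],
         labels = as.list(codes[keep]))
}

#' Build ICD-10-CM training examples from a corpus
#'
#' Per document: sections are cleaned and number-converted, DD is combined
#' with CC, extracted MH keywords are appended, and the combination-code
#' filter rewrites the merged text; labels are the gold CM codes with
#' external cause codes removed. Each stage can be toggled for ablation
#' studies.
#'
#' @param corpus A corpus tibble.
#' @param rules A [rule_tables()] bundle.
#' @param use_mh_keywords Append MH keyword matches? Default `TRUE`.
#' @param number_convert Rewrite essential numbers as words before digit
#'   removal? When `FALSE` digits are removed without conversion.
#' @param combination_filter Apply the combination-code filter? Default
#'   `TRUE`.
#' @param remove_external Drop external cause codes (V01-Y98) from labels?
#'   Default `TRUE`.
#' @return A training-example tibble (`doc_id`, `input_text`, `labels`);
#'   documents whose pipeline output is empty raise an error naming the
#'   document.
#' @export
build_cm_examples <- function(corpus, rules,
                              use_mh_keywords = TRUE,
                              number_convert = TRUE,
                              combination_filter = TRUE,
                              remove_external = TRUE) {
  pats <- if (number_convert) rules$number_patterns else
    default_number_patterns()[0, ]
  prep <- function(x) convert_numbers(clean_text(x), pats)
  dd <- prep(corpus$dd); cc <- prep(corpus$cc); mh <- prep(corpus$mh)
  texts <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    base <- tryCatch(combine_cc(dd[i], cc[i]), error = function(e) "")
    if (use_mh_keywords) {
      kw <- extract_mh_keywords(mh[i], rules$keyword_rules)
      base <- stringr::str_squish(paste(base, paste(kw, collapse = " ")))
    }
    if (combination_filter) {
      base <- apply_combination_filter(base, rules$combination_rules)
    }
    base
  })
  if (any(!nzchar(texts))) {
    stop("empty pipeline output for document(s): ",
         paste(corpus$doc_id[!nzchar(texts)], collapse = ", "),
         call. = FALSE)
  }
  labels <- purrr::map(corpus$gold_cm, function(g) {
    if (remove_external) remove_external_cause_codes(g) else g
  })
  tibble(doc_id = corpus$doc_id, input_text = texts, labels = labels)
}
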