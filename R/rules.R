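# Rule tables are curated inputs produced with disease coders, not learned
# from data. On disk they are tab-separated UTF-8, one rule per line, "#"
# comments allowed.

read_rule_tsv <- function(path, cols) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0) {
    out <- tibble(!!!stats::setNames(rep(list(character(0)), length(cols)),
                                     cols))
    return(out)
  }
  parts <- stringr::str_split_fixed(lines, "\t", length(cols))
  out <- as_tibble(as.data.frame(parts, stringsAsFactors = FALSE))
  names(out) <- cols
  dplyr::mutate(out, dplyr::across(dplyr::everything(), trimws))
}

#' Read a keyword-rule table
#'
#' Keyword rules map a pre-cleaned clinical phrase found in the medical
#' history (MH) or special examination (SE) section to one or more ICD-10
#' codes. TSV columns: `phrase`, comma-separated `codes`, `section`
#' (`MH` or `SE`).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `phrase` (character), `codes`
#'   (list of character), `section`.
#' @export
read_keyword_rules <- function(path) {
  df <- read_rule_tsv(path, c("phrase", "codes", "section"))
  validate_keyword_rules(tibble(
    phrase = df$phrase,
    codes = purrr::map2(stringr::str_split(df$codes, ","),
                        toupper(df$section), function(cs, sec) {
      axis <- if (sec == "SE") "PCS" else "CM"
      normalize_icd(trimws(cs[nzchar(trimws(cs))]), axis)
    }),
    section = toupper(df$section)
  ))
}

validate_keyword_rules <- function(rules) {
  stopifnot(all(c("phrase", "codes", "section") %in% names(rules)))
  rules$phrase <- as.character(rules$phrase)
  if (any(!nzchar(rules$phrase))) stop("empty keyword phrase", call. = FALSE)
  if (any(rules$phrase != clean_text(rules$phrase))) {
    stop("keyword phrases must be pre-cleaned (lowercase, no punctuation)",
         call. = FALSE)
  }
  if (!all(rules$section %in% c("MH", "SE"))) {
    stop("keyword rule section must be MH or SE", call. = FALSE)
  }
  as_tibble(rules)
}

#' Read a combination-code rule table
#'
#' A combination code represents a diagnosis together with one or more
#' comorbidities in a single ICD-10-CM code (e.g. hypertensive heart and
#' chronic kidney disease with heart failure). Each rule has a trigger
#' phrase, companion checks (each a set of alternative phrases, any one of
#' which satisfies the check), the combination code, and replacement text
#' (the combination code's definition). TSV columns: `trigger`,
#' `companions` (groups separated by `;`, alternatives within a group by
#' `|`), `combo_code`, `replacement`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `trigger`, `companions` (list of list of
#'   character), `combo_code`, `replacement`.
#' @export
read_combination_rules <- function(path) {
  df <- read_rule_tsv(path, c("trigger", "companions", "combo_code",
                              "replacement"))
  validate_combination_rules(tibble(
    trigger = df$trigger,
    companions = purrr::map(stringr::str_split(df$companions, ";"),
                            function(gs) {
      purrr::map(gs[nzchar(trimws(gs))],
                 ~ trimws(stringr::str_split_1(.x, "\\|")))
    }),
    combo_code = purrr::map_chr(df$combo_code, normalize_icd, axis = "CM"),
    replacement = df$replacement
  ))
}

validate_combination_rules <- function(rules) {
  stopifnot(all(c("trigger", "companions", "combo_code", "replacement") %in%
                  names(rules)))
  if (any(!nzchar(rules$trigger)) || any(!nzchar(rules$replacement))) {
    stop("combination rules need non-empty trigger and replacement",
         call. = FALSE)
  }
  if (any(lengths(rules$companions) == 0)) {
    stop("combination rules need at least one companion check",
         call. = FALSE)
  }
  as_tibble(rules)
}

#' Read an ICD code definition table
#'
#' Official textual definitions, one per code; used to build definition
#' training pairs. TSV columns: `code`, `definition`.
#'
#' @param path Path to the TSV.
#' @param axis `"CM"` or `"PCS"`.
#' @return A tibble with columns `code`, `definition`.
#' @export
read_definitions <- function(path, axis = "CM") {
  df <- read_rule_tsv(path, c("code", "definition"))
  if (any(!nzchar(df$definition))) stop("empty definition", call. = FALSE)
  tibble(code = normalize_icd(df$code, axis), definition = df$definition)
}

#' Bundle the rule tables a coding pipeline consumes
#'
#' @param keyword_rules Keyword-rule tibble (MH and SE rows together); see
#'   [read_keyword_rules()].
#' @param combination_rules Combination-rule tibble; see
#'   [read_combination_rules()].
#' @param definitions Code definition tibble; see [read_definitions()].
#' @param number_patterns Essential-number pattern tibble; see
#'   [default_number_patterns()].
#' @return A `rule_tables` list.
#' @export
rule_tables <- function(keyword_rules = NULL, combination_rules = NULL,
                        definitions = NULL,
                        number_patterns = default_number_patterns()) {
  empty_kw <- tibble(phrase = character(0), codes = list(),
                     section = character(0))
  empty_cb <- tibble(trigger = character(0), companions = list(),
                     combo_code = character(0), replacement = character(0))
  empty_df <- tibble(code = character(0), definition = character(0))
  structure(list(
    keyword_rules = if (is.null(keyword_rules)) empty_kw
                    else validate_keyword_rules(keyword_rules),
    combination_rules = if (is.null(combination_rules)) empty_cb
                        else validate_combination_rules(combination_rules),
    definitions = definitions %||% empty_df,
    number_patterns = number_patterns
  ), class = "rule_tables")
}

#' Illustrative default rule tables
#'
#' A small editable starter set shipped with the package: ~20 chronic-disease
#' MH keywords, a handful of SE procedure keywords, three hypertension-family
#' combination rules and matching definitions. Real deployments supply full
#' tables curated with their disease coders.
#'
#' @return A [rule_tables()] bundle.
#' @export
default_rule_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "autoicd",
                                 mustWork = TRUE)
  rule_tables(
    keyword_rules = read_keyword_rules(ext("keyword_rules.tsv")),
    combination_rules = read_combination_rules(ext("combination_rules.tsv")),
    definitions = read_definitions(ext("cm_definitions.tsv")),
    number_patterns = read_number_patterns(ext("number_patterns.tsv"))
  )
}

#' @export
print.rule_tables <- function(x, ...) {
  cat("<rule_tables>", nrow(x$keyword_rules), "keyword rules,",
      nrow(x$combination_rules), "combination rules,",
      nrow(x$definitions), "definitions,",
      nrow(x$number_patterns), "number patterns\n")
  invisible(x)
}
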