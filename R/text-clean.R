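#' Common clinical text cleaning
#'
#' Shared first-stage preprocessing for every section: punctuation is
#' replaced by a single space (so tokens never glue together), characters
#' outside basic Latin letters, digits and space are removed (discharge
#' summaries from bilingual hospitals interleave non-Latin names of people,
#' places and transfer hospitals, which carry no coding signal), whitespace
#' is collapsed, and the result is lowercased. Digits are preserved here;
#' [convert_numbers()] handles them.
#'
#' @param raw Character vector; `NA` passes through as `""`.
#' @return Cleaned character vector. Idempotent.
#' @examples
#' clean_text("Urinary tract infection, site not specified.")
#' @export
clean_text <- function(raw) {
  x <- ifelse(is.na(raw), "", as.character(raw))
  x <- stringr::str_remove_all(x, "[^\\x01-\\x7F]")  # non-Latin: removed
  x <- tolower(x)
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ") # punctuation -> space
  stringr::str_squish(x)
}

#' Drop null and duplicate documents
#'
#' Documents whose every section is empty after cleaning are dropped; among
#' documents with identical cleaned section tuples only the first is kept.
#' Order is preserved.
#'
#' @param corpus A corpus tibble.
#' @return The filtered corpus.
#' @export
drop_null_and_duplicates <- function(corpus) {
  keys <- purrr::pmap_chr(corpus[SECTION_COLS], function(...) {
    paste(clean_text(c(...)), collapse = "\x1f")
  })
  keep <- nzchar(gsub("\x1f", "", keys, fixed = TRUE)) & !duplicated(keys)
  corpus[keep, ]
}

#' Convert an integer to English cardinal words
#'
#' Supports 0-999 with hyphenated compounds ("thirty-six") as used when
#' essential clinical numbers are written back as words.
#'
#' @param n Integer vector in \code{[0, 999]}.
#' @return Character vector of number words.
#' @examples
#' number_to_words(c(0, 4, 36, 115))
#' @export
number_to_words <- function(n) {
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 0L) || any(n > 999L)) {
    stop("number_to_words supports integers 0-999", call. = FALSE)
  }
  ones <- c("one", "two", "three", "four", "five", "six", "seven", "eight",
            "nine", "ten", "eleven", "twelve", "thirteen", "fourteen",
            "fifteen", "sixteen", "seventeen", "eighteen", "nineteen")
  tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
            "eighty", "ninety")
  below100 <- function(k) {
    if (k == 0L) return("")
    if (k < 20L) return(ones[k])
    t <- tens[k %/% 10L - 1L]
    if (k %% 10L == 0L) t else paste0(t, "-", ones[k %% 10L])
  }
  vapply(n, function(k) {
    if (k == 0L) return("zero")
    h <- k %/% 100L
    r <- k %% 100L
    parts <- character(0)
    if (h > 0L) parts <- paste(ones[h], "hundred")
    if (r > 0L) parts <- c(parts, below100(r))
    paste(parts, collapse = " ")
  }, character(1))
}

#' Default essential-number patterns
#'
#' Patterns whose numeric slot is clinically meaningful and must survive
#' digit removal: disease type ("type 2 diabetes mellitus"), chronic-disease
#' stage ("stage 4 chronic kidney disease"), tumour/lymphoma grade,
#' pregnancy weeks ("36 weeks gestation of pregnancy") and clinical scales
#' ("modified rankin scale 0"). `{n}` marks the integer slot in the matcher
#' and `{w}` receives the number word in the template. The set is
#' user-extensible: pass additional rows or load a TSV with
#' [read_number_patterns()].
#'
#' @return A tibble with columns `name`, `matcher`, `template`.
#' @export
default_number_patterns <- function() {
  tibble(
    name     = c("type", "stage", "grade", "weeks-gestation", "scale"),
    matcher  = c("type {n}", "stage {n}", "grade {n}",
                 "{n} weeks gestation", "scale {n}"),
    template = c("type {w}", "stage {w}", "grade {w}",
                 "{w} weeks gestation", "scale {w}")
  )
}

pattern_regex <- function(matcher) {
  esc <- stringr::str_replace_all(matcher, "([.^$*+?()\\[\\]|\\\\])", "\\\\\\1")
  paste0("\\b", sub("\\{n\\}", "(\\\\d{1,3})", esc), "\\b")
}

#' Rewrite essential numbers as words, then remove all digits
#'
#' Each essential-pattern occurrence has its integer rewritten in English
#' words; afterwards every remaining token containing a digit (dates,
#' physiological values, line headers) is deleted, as those are
#' uninformative for code assignment. The output contains no digit
#' characters and the operation is idempotent.
#'
#' @param text Cleaned character vector (see [clean_text()]).
#' @param patterns Essential-number pattern tibble; see
#'   [default_number_patterns()]. Use a zero-row tibble to remove all
#'   numbers without conversion.
#' @return Digit-free character vector.
#' @examples
#' convert_numbers("stage 4 chronic kidney disease")
#' convert_numbers("admitted 2020 01 03 wbc 15400")
#' @export
convert_numbers <- function(text, patterns = default_number_patterns()) {
  x <- as.character(text)
  for (i in seq_len(nrow(patterns))) {
    rx <- pattern_regex(patterns$matcher[i])
    tmpl <- patterns$template[i]
    x <- stringr::str_replace_all(x, rx, function(m) {
      num <- suppressWarnings(as.integer(stringr::str_extract(m, "\\d+")))
      words <- number_to_words(num)
      vapply(words, function(w) sub("{w}", w, tmpl, fixed = TRUE),
             character(1), USE.NAMES = FALSE)
    })
  }
  x <- stringr::str_replace_all(x, "\\S*[0-9]\\S*", " ")
  stringr::str_squish(x)
}

#' Read an essential-number pattern table
#'
#' Tab-separated, UTF-8, one pattern per line with columns
#' `name`, `matcher`, `template`; `#` starts a comment.
#'
#' @param path Path to the TSV.
#' @return A pattern tibble as in [default_number_patterns()].
#' @export
read_number_patterns <- function(path) {
  df <- read_rule_tsv(path, c("name", "matcher", "template"))
  stopifnot(all(grepl("{n}", df$matcher, fixed = TRUE)))
  df
}
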