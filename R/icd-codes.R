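#' Normalize ICD-10 codes
#'
#' Canonicalizes ICD-10-CM or ICD-10-PCS code strings: whitespace is
#' stripped, letters are uppercased, and for CM codes the category dot is
#' restored when an export has dropped it (`"N390"` becomes `"N39.0"`).
#' After normalization, equality of code strings is plain string equality.
#'
#' @param code Character vector of raw code strings.
#' @param axis `"CM"` (diagnosis) or `"PCS"` (procedure).
#' @return Character vector of normalized codes.
#' @examples
#' normalize_icd(c("n39.0", " N390 "), "CM")
#' normalize_icd("0dj08zz", "PCS")
#' @export
normalize_icd <- function(code, axis = c("CM", "PCS")) {
  axis <- match.arg(axis)
  if (length(code) == 0) return(character(0))
  x <- toupper(gsub("\\s+", "", as.character(code)))
  if (axis == "CM") {
    # restore the dot after the 3-character category when absent
    no_dot <- !grepl(".", x, fixed = TRUE) & nchar(x) > 3
    x[no_dot] <- paste0(substr(x[no_dot], 1, 3), ".",
                        substring(x[no_dot], 4))
  }
  bad <- !is_valid_icd(x, axis)
  if (any(bad)) {
    stop("invalid ICD-10-", axis, " code(s): ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Validate normalized ICD-10 code shapes
#'
#' CM codes are a letter, two alphanumerics, and an optional dot followed by
#' one to four alphanumerics; PCS codes are seven-character alphanumeric
#' strings.
#'
#' @inheritParams normalize_icd
#' @return Logical vector.
#' @export
is_valid_icd <- function(code, axis = c("CM", "PCS")) {
  axis <- match.arg(axis)
  if (axis == "CM") {
    grepl("^[A-Z][A-Z0-9]{2}(\\.[A-Z0-9]{1,4})?$", code)
  } else {
    grepl("^[A-Z0-9]{7}$", code)
  }
}

#' Identify external cause codes (V01-Y98)
#'
#' External cause codes describe the circumstances of injuries and
#' poisonings. They are seldom supported by discharge-summary text and do
#' not affect disease-related-group payment, so coding pipelines drop them
#' from the label set. A code is external-cause when its 3-character
#' category falls lexicographically within \code{[V01, Y98]}.
#'
#' @param code Character vector of normalized CM codes.
#' @return Logical vector.
#' @examples
#' is_external_cause(c("N39.0", "V01.0", "Y98", "U07.1"))
#' @export
is_external_cause <- function(code) {
  cat3 <- substr(gsub(".", "", code, fixed = TRUE), 1, 3)
  grepl("^[A-Z][0-9]{2}$", cat3) & cat3 >= "V01" & cat3 <= "Y98"
}

#' Construct a label space
#'
#' A label space is the ordered, unique code vocabulary that fixes one-hot
#' label positions for a classifier. Order is lexicographic so positions are
#' reproducible across runs on the same corpus.
#'
#' @param codes Character vector of normalized codes.
#' @param axis `"CM"` or `"PCS"`.
#' @return A `label_space` object (character vector with an `axis`
#'   attribute).
#' @export
label_space <- function(codes, axis = c("CM", "PCS")) {
  axis <- match.arg(axis)
  codes <- sort(unique(normalize_icd(codes, axis)))
  structure(codes, axis = axis, class = "label_space")
}

#' Build the label space observed in a corpus
#'
#' Sorted unique union of the gold codes on one axis across all documents.
#'
#' @param corpus A discharge corpus tibble (see [read_corpus()]).
#' @param axis `"CM"` or `"PCS"`.
#' @return A [label_space()] object.
#' @export
build_label_space <- function(corpus, axis = c("CM", "PCS")) {
  axis <- match.arg(axis)
  col <- if (axis == "CM") "gold_cm" else "gold_pcs"
  codes <- unique(unlist(corpus[[col]], use.names = FALSE))
  if (length(codes) == 0) {
    warning("no ", axis, " codes observed; label space is empty",
            call. = FALSE)
    codes <- character(0)
  }
  label_space(codes, axis)
}

#' @export
print.label_space <- function(x, ...) {
  cat("<label_space> axis=", attr(x, "axis"), ", ", length(x), " codes\n",
      sep = "")
  if (length(x)) print(utils::head(unclass(x), 10))
  invisible(x)
}
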