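#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

SECTION_COLS <- c("dd", "sm", "se", "mh", "cc")

#' Assemble and validate a discharge corpus
#'
#' A corpus is a tibble with one row per hospitalization: a unique `doc_id`,
#' five optional text sections — discharge diagnoses (`dd`), surgical method
#' (`sm`), special examination (`se`), medical history (`mh`), comorbidity
#' and complication (`cc`) — and two list-columns `gold_cm` / `gold_pcs`
#' holding the coder-assigned code sets. Absent sections are `NA`; gold sets
#' hold 1-20 codes when non-empty.
#'
#' @param docs A data frame with the columns above (gold columns may be
#'   character vectors wrapped in lists).
#' @return A validated corpus tibble.
#' @export
discharge_corpus <- function(docs) {
  docs <- as_tibble(docs)
  for (s in SECTION_COLS) {
    if (!s %in% names(docs)) docs[[s]] <- NA_character_
    docs[[s]] <- as.character(docs[[s]])
    docs[[s]][!is.na(docs[[s]]) & !nzchar(trimws(docs[[s]]))] <- NA_character_
  }
  if (!"doc_id" %in% names(docs)) stop("corpus needs a doc_id column")
  docs$doc_id <- as.character(docs$doc_id)
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate doc_id: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (g in c("gold_cm", "gold_pcs")) {
    if (!g %in% names(docs)) docs[[g]] <- list(character(0))[rep(1, nrow(docs))]
    axis <- if (g == "gold_cm") "CM" else "PCS"
    docs[[g]] <- purrr::map(docs[[g]], function(v) {
      v <- unlist(v, use.names = FALSE)
      if (is.null(v) || length(v) == 0 || all(is.na(v))) return(character(0))
      sort(unique(normalize_icd(v[!is.na(v)], axis)))
    })
    n_codes <- lengths(docs[[g]])
    if (any(n_codes > 20)) {
      stop("gold ", axis, " sets must hold at most 20 codes (doc ",
           docs$doc_id[which(n_codes > 20)[1]], ")", call. = FALSE)
    }
  }
  empty <- rowSums(!is.na(as.matrix(docs[SECTION_COLS]))) == 0
  if (any(empty)) {
    stop("document(s) with every section empty: ",
         paste(docs$doc_id[empty], collapse = ", "), call. = FALSE)
  }
  docs[c("doc_id", SECTION_COLS, "gold_cm", "gold_pcs")]
}

#' Read a discharge corpus from JSON-lines
#'
#' One JSON object per line with keys `doc_id`, `dd`, `sm`, `se`, `mh`,
#' `cc`, `gold_cm`, `gold_pcs`; sections may be `null`. Codes are normalized
#' on read.
#'
#' @param path Path to a JSONL file.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(discharge_corpus(tibble(doc_id = character(0)))[0, ])
  }
  rows <- purrr::imap(lines, function(l, i) {
    obj <- tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSON on line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(obj$doc_id)) stop("missing doc_id on line ", i, call. = FALSE)
    sec <- lapply(SECTION_COLS, function(s) {
      v <- obj[[s]]
      if (is.null(v) || length(v) == 0 || is.na(v[1])) NA_character_
      else as.character(v[1])
    })
    names(sec) <- SECTION_COLS
    tibble(doc_id = as.character(obj$doc_id), !!!sec,
           gold_cm = list(as.character(obj$gold_cm %||% character(0))),
           gold_pcs = list(as.character(obj$gold_pcs %||% character(0))))
  })
  discharge_corpus(dplyr::bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a discharge corpus to JSON-lines
#'
#' Inverse of [read_corpus()]: the round trip reproduces the corpus exactly,
#' including absent sections (written as `null`) and unicode text.
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- purrr::pmap_chr(corpus, function(doc_id, dd, sm, se, mh, cc,
                                            gold_cm, gold_pcs) {
    jsonlite::toJSON(
      list(doc_id = doc_id, dd = dd, sm = sm, se = se, mh = mh, cc = cc,
           gold_cm = I(gold_cm), gold_pcs = I(gold_pcs)),
      auto_unbox = TRUE, na = "null")
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Split a corpus into training and validation sets
#'
#' Documents are assigned by shuffling ids with a seeded generator and
#' slicing: the first `round(n * ratio)` go to training, the rest to
#' validation. The split is an exact partition and is deterministic given
#' the seed. No stratification is applied.
#'
#' @param corpus A corpus tibble with at least 2 documents.
#' @param ratio Training fraction in (0, 1); default 0.9 (a 9:1 split).
#' @param seed Integer seed.
#' @return A list with elements `train` and `valid`.
#' @export
split_train_valid <- function(corpus, ratio = 0.9, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- nrow(corpus)
  if (n < 2) stop("need at least 2 documents to split", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- round(n * ratio)
  list(train = corpus[sort(idx[seq_len(n_train)]), ],
       valid = corpus[sort(idx[-seq_len(n_train)]), ])
}
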