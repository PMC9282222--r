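# Seeded synthetic discharge-summary generator. Surface text is
# template-based (code phrases in carrier sentences with filler narrative),
# not free text: tests need exact control over which phrases appear in
# which section. Alongside the corpus the generator emits a manifest
# recording which structural mechanism produced each gold code, so ablation
# tests read ground truth instead of re-inferring it.

#' Synthetic-corpus configuration
#'
#' Defaults mirror the fractions reported for real discharge-summary data:
#' chronic diseases missing from DD in ~15% of cases, external cause codes
#' in 2.73% of cases, surgical method present in 58% of cases, 1-20 codes
#' per case, and mean section word counts of 31 (DD), 11 (SM), 86 (SE),
#' 149 (MH) and 5 (CC). Fractions without a reported value (CC presence,
#' combination cases, number-sensitive codes, definition phrasing, SE
#' presence, PCS leakage into DD, noise rates) are fixed at values
#' realistic for inpatient records; see the methods vignette.
#'
#' @param n_docs Number of documents.
#' @param n_cm_codes,n_pcs_codes Vocabulary sizes per axis (>= 10 each).
#' @param codes_per_doc Integer range of gold CM codes per document.
#' @param frac_chronic_only_in_mh Fraction of documents whose chronic-code
#'   phrase appears only in MH, never in DD.
#' @param frac_external_cause Fraction of external cause codes in the CM
#'   vocabulary and of documents carrying one (textually unsupported).
#' @param frac_with_sm Fraction of documents with a surgical-method section.
#' @param frac_with_se Fraction with a special-examination section.
#' @param frac_with_cc Fraction with a comorbidity-and-complication section
#'   whose code phrase appears only in CC.
#' @param frac_combination_cases Fraction of documents mentioning a
#'   combination-rule trigger plus companions while gold carries the
#'   combination code.
#' @param frac_number_sensitive Fraction of CM codes arranged in
#'   stage-groups distinguishable only by an essential number.
#' @param frac_definition_phrasing Probability a DD mention uses the code's
#'   official-definition phrasing instead of its record phrasing.
#' @param frac_pcs_in_dd Probability an SM-realized procedure also leaves a
#'   status-post mention in DD.
#' @param noise Named list of per-section injection rates: `digit`
#'   (physiological values), `date`, `chinese` (non-Latin filler tokens).
#' @param section_length_targets Named mean word counts for dd/sm/se/mh/cc.
#' @param seed Integer seed; the generator is reproducible end to end.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_docs = 1000L,
                             n_cm_codes = 120L,
                             n_pcs_codes = 60L,
                             codes_per_doc = c(1L, 20L),
                             frac_chronic_only_in_mh = 0.15,
                             frac_external_cause = 0.0273,
                             frac_with_sm = 0.58,
                             frac_with_se = 0.5,
                             frac_with_cc = 0.35,
                             frac_combination_cases = 0.10,
                             frac_number_sensitive = 0.20,
                             frac_definition_phrasing = 0.15,
                             frac_pcs_in_dd = 0.3,
                             noise = list(digit = 0.5, date = 0.3,
                                          chinese = 0.3),
                             section_length_targets = c(dd = 31, sm = 11,
                                                        se = 86, mh = 149,
                                                        cc = 5),
                             seed = 42L) {
  fr <- c(frac_chronic_only_in_mh, frac_external_cause, frac_with_sm,
          frac_with_se, frac_with_cc, frac_combination_cases,
          frac_number_sensitive, frac_definition_phrasing, frac_pcs_in_dd)
  stopifnot(all(fr >= 0), all(fr <= 1), n_docs >= 0,
            all(section_length_targets > 0),
            codes_per_doc[1] >= 1, codes_per_doc[2] >= codes_per_doc[1])
  structure(as.list(environment()), class = "synthetic_config")
}

subseed <- function(seed, k) {
  (abs(as.numeric(seed)) * 7 + 1103515245 * k) %% 2147483647
}

# Deterministic pseudo-clinical word stock: CV syllable words, optionally
# suffixed, unique within and across pools by construction.
make_word_pool <- function(n, suffixes = "") {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "br", "cr", "st", "pl", "tr", "gl")
  vow <- c("a", "e", "i", "o", "u", "ae", "ia", "ou")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:3, 1)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE), collapse = ""),
                sample(suffixes, 1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

random_cm_code <- function(n, letters_pool) {
  paste0(sample(letters_pool, n, replace = TRUE),
         sprintf("%02d", sample(0:98, n, replace = TRUE)), ".",
         sample(0:9, n, replace = TRUE))
}

#' Generate a synthetic coding world
#'
#' Builds the code vocabularies, surface-phrase lexicon, definitions and
#' rule tables that a corpus is generated against. Deterministic given the
#' config seed. The world always contains: external cause codes at the
#' configured vocabulary fraction (`round(n_cm_codes *
#' frac_external_cause)`), at least one combination-code family (trigger
#' plus two companion checks resolving to a distinct combination code,
#' mirroring the hypertensive heart-and-kidney-disease pattern), and
#' stage-groups of codes whose phrases differ only in an essential number
#' (the type-1/type-2 diabetes contrast).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_world` list: `cm_codes`, `pcs_codes`, `phrase_map`,
#'   `rules` (a [rule_tables()] bundle), `config`.
#' @export
generate_world <- function(config) {
  stopifnot(config$n_cm_codes >= 10, config$n_pcs_codes >= 10)
  n_ext <- round(config$n_cm_codes * config$frac_external_cause)
  if (config$frac_external_cause > 0 && n_ext == 0) {
    stop("frac_external_cause > 0 but the vocabulary rounds to zero ",
         "external cause codes; request more CM codes or a larger fraction",
         call. = FALSE)
  }
  withr::with_seed(subseed(config$seed, 1), {
    n_cm <- config$n_cm_codes
    n_reg <- n_cm - n_ext
    # unique code strings per axis
    reg <- unique(random_cm_code(n_reg * 4, setdiff(LETTERS, c("V", "W",
                                                               "X", "Y"))))
    reg <- reg[!is_external_cause(reg)][seq_len(n_reg)]
    ext <- character(0)
    if (n_ext > 0) {
      ext <- unique(paste0(sample(c("V", "W", "X", "Y"), n_ext * 4,
                                  replace = TRUE),
                           sprintf("%02d", sample(1:98, n_ext * 4,
                                                  replace = TRUE)), ".",
                           sample(0:9, n_ext * 4, replace = TRUE)))
      ext <- ext[is_external_cause(ext)][seq_len(n_ext)]
    }
    pcs <- unique(vapply(seq_len(config$n_pcs_codes * 3), function(i) {
      paste0(paste(sample(c(0:9, LETTERS[1:8]), 7, replace = TRUE),
                   collapse = ""))
    }, character(1)))[seq_len(config$n_pcs_codes)]

    heads <- make_word_pool(n_reg, c("itis", "osis", "emia", "oma", "opathy"))
    defheads <- make_word_pool(n_cm, c("us", "um", "ius"))
    mods <- make_word_pool(25, "")
    filler <- make_word_pool(90, "")
    pcs_heads <- make_word_pool(config$n_pcs_codes,
                                c("ectomy", "oscopy", "otomy", "plasty"))

    # number-sensitive stage groups of 3 sharing a base head
    n_ns <- 3 * (round(n_cm * config$frac_number_sensitive) %/% 3)
    # combination families: 2 (trigger, 2 companions, combo), plain codes
    n_combo_fam <- 2L
    kinds <- rep("ordinary", n_reg)
    idx <- seq_len(n_reg)
    ns_idx <- utils::head(idx, n_ns)
    kinds[ns_idx] <- "number"
    free <- setdiff(idx, ns_idx)
    fam_idx <- matrix(utils::head(free, 4 * n_combo_fam), ncol = 4,
                      byrow = TRUE)
    kinds[fam_idx[, 1]] <- "trigger"
    kinds[fam_idx[, 2]] <- "companion"
    kinds[fam_idx[, 3]] <- "companion"
    kinds[fam_idx[, 4]] <- "combo"
    free <- setdiff(free, as.vector(fam_idx))
    n_chronic <- round(0.25 * length(free))
    kinds[utils::head(free, n_chronic)] <- "chronic"

    stage_words <- c("one", "two", "three", "four", "five", "six")
    stage_digit <- as.character(1:6)
    phrases <- vector("list", n_reg)
    raw_forms <- vector("list", n_reg)
    ns_base <- make_word_pool(max(1, n_ns %/% 3), "osis")
    for (i in idx) {
      if (kinds[i] == "number") {
        grp <- (match(i, ns_idx) - 1) %/% 3 + 1
        pos <- (match(i, ns_idx) - 1) %% 3 + 1
        st <- c(1, 3, 5)[pos]
        phrases[[i]] <- paste("stage", stage_words[st], ns_base[grp])
        raw_forms[[i]] <- paste("stage", stage_digit[st], ns_base[grp])
      } else {
        n_var <- sample(1:3, 1)
        phrases[[i]] <- unique(paste(sample(mods, n_var, replace = FALSE),
                                     heads[i]))
        raw_forms[[i]] <- phrases[[i]]
      }
    }
    definitions <- ifelse(kinds == "combo",
                          vapply(phrases, `[`, character(1), 1),
                          paste(defheads[seq_len(n_reg)], "morbus"))

    ext_defheads <- defheads[n_reg + seq_len(n_ext)]
    ext_phrases <- if (n_ext > 0) {
      as.list(paste("externus", ext_defheads))
    } else {
      list()
    }
    ext_defs <- if (n_ext > 0) paste(ext_defheads, "externus") else
      character(0)
    cm_codes <- tibble(code = normalize_icd(c(reg, ext), "CM"),
                       kind = c(kinds, rep("external", n_ext)),
                       phrases = c(phrases, ext_phrases),
                       raw_forms = c(raw_forms,
                                     as.list(rep(NA_character_, n_ext))),
                       definition = c(definitions, ext_defs))

    pcs_via <- sample(c("SM", "SE"), config$n_pcs_codes, replace = TRUE,
                      prob = c(0.7, 0.3))
    pcs_codes <- tibble(code = pcs,
                        via = pcs_via,
                        phrases = purrr::map(seq_len(config$n_pcs_codes),
                                             ~ paste(sample(mods, 1),
                                                     pcs_heads[.x])))

    # rule tables derived from the world
    chronic <- cm_codes[cm_codes$kind == "chronic", ]
    kw_mh <- tibble(phrase = unlist(chronic$phrases),
                    codes = rep(purrr::map(chronic$code, identity),
                                lengths(chronic$phrases)),
                    section = "MH")
    se_codes <- pcs_codes[pcs_codes$via == "SE", ]
    kw_se <- tibble(phrase = unlist(se_codes$phrases),
                    codes = rep(purrr::map(se_codes$code, identity),
                                lengths(se_codes$phrases)),
                    section = "SE")
    fam <- purrr::map_dfr(seq_len(n_combo_fam), function(f) {
      tr <- cm_codes[fam_idx[f, 1], ]
      c1 <- cm_codes[fam_idx[f, 2], ]
      c2 <- cm_codes[fam_idx[f, 3], ]
      cb <- cm_codes[fam_idx[f, 4], ]
      tibble(trigger = tr$phrases[[1]][1],
             companions = list(list(c1$phrases[[1]], c2$phrases[[1]])),
             combo_code = cb$code, replacement = cb$definition,
             trigger_code = tr$code,
             companion_codes = list(c(c1$code, c2$code)))
    })
    rules <- rule_tables(
      keyword_rules = dplyr::bind_rows(kw_mh, kw_se),
      combination_rules = fam[c("trigger", "companions", "combo_code",
                                "replacement")],
      definitions = tibble(code = cm_codes$code,
                           definition = cm_codes$definition))

    phrase_map <- tidyr::unnest(
      tibble(code = cm_codes$code, phrase = cm_codes$phrases,
             kind = cm_codes$kind),
      "phrase")
    phrase_map <- phrase_map[phrase_map$kind != "external", ]
    # definition phrasings are realizable in DD too
    phrase_map <- dplyr::distinct(dplyr::bind_rows(
      phrase_map,
      tibble(code = cm_codes$code, phrase = cm_codes$definition,
             kind = cm_codes$kind)[cm_codes$kind != "external", ]))

    structure(list(cm_codes = cm_codes, pcs_codes = pcs_codes,
                   families = fam, phrase_map = phrase_map,
                   rules = rules, config = config),
              class = "synthetic_world")
  })
}

cjk_noise_tokens <- function(n) {
  pool <- c("醫院", "病人", "臺北",
            "轉院", "主治", "林口")
  sample(pool, n, replace = TRUE)
}

digit_noise <- function() {
  paste("wbc", sample(3000:20000, 1), "hb", sample(70:160, 1))
}

date_noise <- function() {
  paste(sample(2018:2020, 1), sprintf("%02d", sample(1:12, 1)),
        sprintf("%02d", sample(1:28, 1)))
}

# sample() without the scalar-x surprise
safe_sample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

word_count <- function(x) {
  if (length(x) == 0) return(0L)
  sum(lengths(strsplit(x, " ", fixed = TRUE)))
}

pad_filler <- function(words, target, filler) {
  need <- max(0L, stats::rpois(1, target) - word_count(words))
  c(words, safe_sample(filler, need, replace = TRUE))
}

#' Generate a synthetic discharge corpus
#'
#' Draws 1-20 gold CM codes per document (plus PCS codes when procedures
#' are assigned) and realizes them as section text according to structural
#' mechanisms: most CM codes leave their phrase in DD (occasionally in
#' official-definition phrasing); a configured fraction of chronic codes
#' appear only in MH; CC-only codes only in CC; combination cases mention
#' trigger and companion phrases while gold carries the combination code;
#' external cause codes leave no text at all; number-sensitive codes are
#' written with their digit ("stage 4 ...") so only number conversion
#' preserves the distinction; SM and SE carry PCS phrases; digit, date and
#' non-Latin noise are injected at the configured rates. Deterministic
#' given the config seed.
#'
#' @param world A [generate_world()] result.
#' @param config A [synthetic_config()] (defaults to the world's).
#' @return A corpus tibble with a `manifest` attribute (tibble `doc_id`,
#'   `code`, `axis`, `mechanism`); retrieve it with [corpus_manifest()].
#' @export
generate_corpus <- function(world, config = world$config) {
  if (config$n_docs < 1) stop("n_docs must be >= 1", call. = FALSE)
  cm <- world$cm_codes
  pcs <- world$pcs_codes
  filler <- withr::with_seed(subseed(config$seed, 2),
                             make_word_pool(90, ""))
  narrative <- withr::with_seed(subseed(config$seed, 3),
                                make_word_pool(60, "gram"))
  realizable <- which(cm$kind %in% c("ordinary", "chronic", "number",
                                     "trigger", "companion", "combo"))
  chronic_idx <- which(cm$kind == "chronic")
  ext_idx <- which(cm$kind == "external")
  sm_pool <- which(pcs$via == "SM")
  se_pool <- which(pcs$via == "SE")
  tgt <- config$section_length_targets

  withr::with_seed(subseed(config$seed, 4), {
    docs <- vector("list", config$n_docs)
    manifest <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("doc%05d", d)
      k <- sample(seq(config$codes_per_doc[1], config$codes_per_doc[2]), 1)
      gold_cm <- character(0)
      man_code <- character(0); man_axis <- character(0)
      man_mech <- character(0)
      dd_words <- character(0)
      mh_words <- character(0)
      cc_words <- character(0)
      used <- integer(0)

      add_man <- function(code, axis, mech) {
        man_code <<- c(man_code, code)
        man_axis <<- c(man_axis, axis)
        man_mech <<- c(man_mech, mech)
      }

      # chronic code realized only in MH
      if (length(chronic_idx) > 0 && stats::runif(1) <
            config$frac_chronic_only_in_mh && length(gold_cm) < k) {
        i <- safe_sample(chronic_idx, 1)
        used <- c(used, i)
        gold_cm <- c(gold_cm, cm$code[i])
        mh_words <- c(mh_words, cm$phrases[[i]][1])
        add_man(cm$code[i], "CM", "mh_only")
      }
      # combination case: trigger + companions in DD, combo code in gold
      if (stats::runif(1) < config$frac_combination_cases &&
            length(gold_cm) < k) {
        f <- sample.int(nrow(world$families), 1)
        fam <- world$families[f, ]
        combo <- fam$combo_code
        comp_phr <- vapply(fam$companions[[1]],
                           function(g) safe_sample(g, 1), character(1))
        dd_words <- c(dd_words, fam$trigger, comp_phr)
        gold_cm <- c(gold_cm, combo)
        used <- c(used, match(c(combo, fam$trigger_code,
                                fam$companion_codes[[1]]), cm$code))
        add_man(combo, "CM", "combination")
      }
      # external cause code: in gold, never in text
      if (length(ext_idx) > 0 && stats::runif(1) <
            config$frac_external_cause && length(gold_cm) < k) {
        i <- safe_sample(ext_idx, 1)
        gold_cm <- c(gold_cm, cm$code[i])
        add_man(cm$code[i], "CM", "external_cause")
      }
      # comorbidity/complication code realized only in CC
      has_cc <- stats::runif(1) < config$frac_with_cc
      if (has_cc && length(gold_cm) < k) {
        i <- safe_sample(setdiff(realizable, used), 1)
        used <- c(used, i)
        gold_cm <- c(gold_cm, cm$code[i])
        cc_words <- c(cc_words, cm$phrases[[i]][1])
        add_man(cm$code[i], "CM", "cc_only")
      }
      # remaining codes realized in DD
      n_rest <- k - length(gold_cm)
      if (n_rest > 0) {
        pool <- setdiff(realizable, used)
        take <- safe_sample(pool, min(n_rest, length(pool)))
        for (i in take) {
          gold_cm <- c(gold_cm, cm$code[i])
          if (cm$kind[i] == "number") {
            dd_words <- c(dd_words, cm$raw_forms[[i]][1])
            add_man(cm$code[i], "CM", "number")
          } else if (stats::runif(1) < config$frac_definition_phrasing &&
                       cm$kind[i] != "combo") {
            dd_words <- c(dd_words, cm$definition[i])
            add_man(cm$code[i], "CM", "dd_definition")
          } else {
            dd_words <- c(dd_words,
                          safe_sample(cm$phrases[[i]], 1))
            add_man(cm$code[i], "CM", "dd_phrase")
          }
        }
      }

      # procedures
      gold_pcs <- character(0)
      sm_txt <- NA_character_
      se_txt <- NA_character_
      has_sm <- stats::runif(1) < config$frac_with_sm
      has_se <- stats::runif(1) < config$frac_with_se
      if (has_sm && length(sm_pool) > 0) {
        take <- safe_sample(sm_pool, min(sample(1:3, 1), length(sm_pool)))
        sm_words <- character(0)
        for (i in take) {
          gold_pcs <- c(gold_pcs, pcs$code[i])
          sm_words <- c(sm_words, pcs$phrases[[i]][1])
          add_man(pcs$code[i], "PCS", "sm_phrase")
          if (stats::runif(1) < config$frac_pcs_in_dd) {
            dd_words <- c(dd_words, "status post", pcs$phrases[[i]][1])
          }
        }
        sm_words <- pad_filler(sm_words, tgt[["sm"]], filler)
        sm_txt <- paste(sm_words, collapse = " ")
      }
      if (has_se && length(se_pool) > 0) {
        n_se <- min(sample(0:2, 1), length(se_pool))
        se_words <- safe_sample(narrative, 5)
        if (n_se > 0) {
          take <- safe_sample(se_pool, n_se)
          for (i in take) {
            gold_pcs <- c(gold_pcs, pcs$code[i])
            se_words <- c(se_words, pcs$phrases[[i]][1])
            add_man(pcs$code[i], "PCS", "se_keyword")
          }
        }
        se_words <- pad_filler(se_words, tgt[["se"]], narrative)
        if (stats::runif(1) < config$noise$digit) {
          se_words <- c(se_words, digit_noise())
        }
        se_txt <- paste(se_words, collapse = " ")
      }

      # assemble sections with noise
      if (stats::runif(1) < config$noise$digit) {
        dd_words <- c(dd_words, digit_noise())
      }
      if (stats::runif(1) < config$noise$chinese) {
        dd_words <- c(dd_words, cjk_noise_tokens(2))
      }
      dd_words <- pad_filler(dd_words, tgt[["dd"]], filler)
      mh_words <- pad_filler(mh_words, tgt[["mh"]], filler)
      if (stats::runif(1) < config$noise$date) {
        mh_words <- c(date_noise(), mh_words)
      }
      if (stats::runif(1) < config$noise$chinese) {
        mh_words <- c(mh_words, cjk_noise_tokens(2))
      }
      if (has_cc) cc_words <- pad_filler(cc_words, tgt[["cc"]], filler)

      docs[[d]] <- tibble(
        doc_id = doc_id,
        dd = paste(dd_words, collapse = " "),
        sm = sm_txt, se = se_txt,
        mh = paste(mh_words, collapse = " "),
        cc = if (has_cc) paste(cc_words, collapse = " ") else NA_character_,
        gold_cm = list(utils::head(gold_cm, 20)),
        gold_pcs = list(utils::head(gold_pcs, 20)))
      manifest[[d]] <- tibble(doc_id = doc_id, code = man_code,
                              axis = man_axis, mechanism = man_mech)
    }
    corpus <- discharge_corpus(dplyr::bind_rows(docs))
    attr(corpus, "manifest") <- dplyr::bind_rows(manifest)
    corpus
  })
}

#' Retrieve the generator's ground-truth manifest
#'
#' @param corpus A corpus produced by [generate_corpus()].
#' @return A tibble (`doc_id`, `code`, `axis`, `mechanism`) recording which
#'   structural mechanism produced each gold code.
#' @export
corpus_manifest <- function(corpus) {
  m <- attr(corpus, "manifest")
  if (is.null(m)) stop("corpus has no generator manifest", call. = FALSE)
  m
}

#' Write a synthetic world and corpus to disk
#'
#' Emits the standard interchange files: `corpus.jsonl`,
#' `manifest.jsonl`, `keyword_rules.tsv`, `combination_rules.tsv`,
#' `definitions.tsv`, `number_patterns.tsv`.
#'
#' @param world A [generate_world()] result.
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(world, corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(corpus, file.path(dir, "corpus.jsonl"))
  man <- corpus_manifest(corpus)
  writeLines(purrr::pmap_chr(man, function(...) {
    jsonlite::toJSON(list(...), auto_unbox = TRUE)
  }), file.path(dir, "manifest.jsonl"))
  r <- world$rules
  kw <- r$keyword_rules
  writeLines(c("# phrase\tcodes\tsection",
               sprintf("%s\t%s\t%s", kw$phrase,
                       purrr::map_chr(kw$codes, paste, collapse = ","),
                       kw$section)),
             file.path(dir, "keyword_rules.tsv"))
  cb <- r$combination_rules
  writeLines(c("# trigger\tcompanions\tcombo_code\treplacement",
               sprintf("%s\t%s\t%s\t%s", cb$trigger,
                       purrr::map_chr(cb$companions, function(gs) {
                         paste(purrr::map_chr(gs, paste, collapse = "|"),
                               collapse = ";")
                       }),
                       cb$combo_code, cb$replacement)),
             file.path(dir, "combination_rules.tsv"))
  writeLines(c("# code\tdefinition",
               sprintf("%s\t%s", r$definitions$code,
                       r$definitions$definition)),
             file.path(dir, "definitions.tsv"))
  np <- r$number_patterns
  writeLines(c("# name\tmatcher\ttemplate",
               sprintf("%s\t%s\t%s", np$name, np$matcher, np$template)),
             file.path(dir, "number_patterns.tsv"))
  invisible(dir)
}
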