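# Ablation harness: train and evaluate the same corpus split under a set
# of named pipeline configurations, one table row per configuration, all
# rows sharing the validation documents so differences reflect the
# preprocessing alone.

#' Stepwise CM preprocessing configurations
#'
#' Five cumulative rows mirroring a preprocessing-added-one-by-one design:
#' baseline (DD+CC with MH keywords, digits removed without conversion),
#' then definition pretraining, external cause code removal, number
#' conversion, and the combination code filter.
#'
#' @return A tibble of toggle columns with a `name` column.
#' @export
default_cm_ablation_configs <- function() {
  tibble(
    name = c("baseline", "+definition", "+external_removal",
             "+number_convert", "+combination_filter"),
    use_mh_keywords     = TRUE,
    definition_pretrain = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    remove_external     = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    number_convert      = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    combination_filter  = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

fit_and_score <- function(ex_train, ex_valid, space, tc, pretrain_defs) {
  init <- NULL
  if (!is.null(pretrain_defs)) {
    init <- pretrain_on_definitions(pretrain_defs, space, tc)
  }
  model <- train_classifier(ex_train, space, tc, init = init)
  scores <- predict_scores(model, ex_valid$input_text)
  pred <- purrr::map(seq_len(nrow(scores)), function(i) {
    as.character(space)[scores[i, ] >= tc$threshold]
  })
  list(model = model, scores = scores, pred = pred)
}

metrics_to_row <- function(name, report) {
  wide <- purrr::map_dfc(seq_len(nrow(report)), function(i) {
    m <- report$metric[i]
    stats::setNames(tibble(report$point[i], report$ci_low[i],
                           report$ci_high[i]),
                    paste0(m, c("", "_low", "_high")))
  })
  dplyr::bind_cols(tibble(name = name), wide, tibble(error = NA_character_))
}

#' Run a CM preprocessing ablation
#'
#' Splits the corpus once, then for each configuration builds the CM
#' examples with that row's toggles, trains the classifier (optionally
#' warm-started on the rule tables' definitions), predicts on the shared
#' validation documents and reports micro precision/recall/F1/AUROC with
#' bootstrap CIs. A configuration that fails yields a row carrying the
#' error message; other rows are still produced.
#'
#' @param corpus A corpus tibble.
#' @param rules A [rule_tables()] bundle.
#' @param configs Configuration tibble; see
#'   [default_cm_ablation_configs()].
#' @param split_ratio,split_seed Train/validation split (default 9:1,
#'   seed 42).
#' @param tc A [train_config()] for every row.
#' @param n_bootstrap,level Bootstrap settings.
#' @return An `ablation_report` tibble, one row per configuration.
#' @export
run_cm_ablation <- function(corpus, rules,
                            configs = default_cm_ablation_configs(),
                            split_ratio = 0.9, split_seed = 42L,
                            tc = train_config(),
                            n_bootstrap = 100L, level = 0.95) {
  if (nrow(configs) < 2) stop("need at least 2 configurations",
                              call. = FALSE)
  sp <- split_train_valid(corpus, split_ratio, split_seed)
  rows <- purrr::map(seq_len(nrow(configs)), function(i) {
    cfg <- configs[i, ]
    tryCatch({
      ex_tr <- build_cm_examples(sp$train, rules,
                                 use_mh_keywords = cfg$use_mh_keywords,
                                 number_convert = cfg$number_convert,
                                 combination_filter = cfg$combination_filter,
                                 remove_external = cfg$remove_external)
      ex_va <- build_cm_examples(sp$valid, rules,
                                 use_mh_keywords = cfg$use_mh_keywords,
                                 number_convert = cfg$number_convert,
                                 combination_filter = cfg$combination_filter,
                                 remove_external = cfg$remove_external)
      space <- label_space(unique(unlist(c(ex_tr$labels, ex_va$labels))),
                           "CM")
      defs <- NULL
      if (isTRUE(cfg$definition_pretrain)) {
        dtab <- rules$definitions
        dtab <- dtab[normalize_icd(dtab$code, "CM") %in%
                       as.character(space), , drop = FALSE]
        if (nrow(dtab) > 0) defs <- build_definition_pairs(dtab, "CM")
      }
      fs <- fit_and_score(ex_tr, ex_va, space, tc, defs)
      rep <- evaluate_predictions(ex_va$labels, fs$pred, space,
                                  scores = fs$scores,
                                  n_bootstrap = n_bootstrap,
                                  level = level, seed = tc$seed)
      metrics_to_row(cfg$name, rep)
    }, error = function(e) {
      tibble(name = cfg$name, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ablation_report", class(out)),
            valid_doc_ids = sp$valid$doc_id)
}

#' Run the ICD-10-PCS strategy comparison
#'
#' One row per section-combination strategy (see [pcs_strategies()]) on a
#' shared split; documents for which a strategy yields no input text are
#' kept with empty predictions so the validation set is identical across
#' rows.
#'
#' @inheritParams run_cm_ablation
#' @param strategies Character vector of strategies; default all five.
#' @return An `ablation_report` tibble, one row per strategy.
#' @export
run_pcs_ablation <- function(corpus, rules, strategies = pcs_strategies(),
                             split_ratio = 0.9, split_seed = 42L,
                             tc = train_config(),
                             n_bootstrap = 100L, level = 0.95) {
  sp <- split_train_valid(corpus, split_ratio, split_seed)
  space <- build_label_space(corpus, "PCS")
  rows <- purrr::map(strategies, function(strat) {
    tryCatch({
      ex_tr <- build_pcs_examples(sp$train, strat, rules, strict = FALSE)
      ex_va <- build_pcs_examples(sp$valid, strat, rules, strict = FALSE)
      trainable <- nzchar(ex_tr$input_text)
      fs <- fit_and_score(ex_tr[trainable, ], ex_va, space, tc, NULL)
      empty <- !nzchar(ex_va$input_text)
      fs$pred[empty] <- list(character(0))
      fs$scores[empty, ] <- 0
      rep <- evaluate_predictions(ex_va$labels, fs$pred, space,
                                  scores = fs$scores,
                                  n_bootstrap = n_bootstrap,
                                  level = level, seed = tc$seed)
      metrics_to_row(strat, rep)
    }, error = function(e) {
      tibble(name = strat, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ablation_report", class(out)),
            valid_doc_ids = sp$valid$doc_id)
}

#' Write an ablation report as TSV
#'
#' Columns follow the conventional layout: method, F1 with CI, precision
#' with CI, recall with CI, AUROC with CI.
#'
#' @param report An `ablation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ablation_tsv <- function(report, path) {
  fmt <- function(p, lo, hi) {
    ifelse(is.na(p), "", sprintf("%.3f (%.3f-%.3f)", p, lo, hi))
  }
  df <- tibble(
    method = report$name,
    micro_f1 = fmt(report$micro_f1, report$micro_f1_low,
                   report$micro_f1_high),
    micro_precision = fmt(report$micro_precision,
                          report$micro_precision_low,
                          report$micro_precision_high),
    micro_recall = fmt(report$micro_recall, report$micro_recall_low,
                       report$micro_recall_high),
    micro_auroc = fmt(report$micro_auroc, report$micro_auroc_low,
                      report$micro_auroc_high),
    error = ifelse(is.na(report$error), "", report$error)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an ablation report
#'
#' Micro-F1 per configuration with bootstrap CI error bars.
#'
#' @param object An `ablation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ablation_report
#' @export
autoplot.ablation_report <- function(object, ...) {
  df <- as_tibble(object)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$micro_f1, y = .data$name)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$micro_f1_low,
                                         xmax = .data$micro_f1_high),
                            height = 0.2) +
    ggplot2::labs(x = "micro F1 (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}
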