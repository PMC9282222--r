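# Micro-averaged evaluation: every document-label cell of the indicator
# matrix counts as one binary decision; true/false positives and negatives
# are pooled over all cells before computing precision, recall, F1 and
# AUROC. Confidence intervals come from a percentile bootstrap that
# resamples documents (the exchangeable unit) with replacement.

#' Build a binary label-indicator matrix
#'
#' @param code_sets List of character vectors of codes (one per document).
#' @param space A [label_space()] (or character vector) fixing columns.
#' @return Numeric 0/1 matrix, documents x labels; codes outside the space
#'   are ignored.
#' @export
label_matrix <- function(code_sets, space) {
  codes <- as.character(space)
  M <- matrix(0, length(code_sets), length(codes),
              dimnames = list(NULL, codes))
  for (i in seq_along(code_sets)) {
    j <- match(code_sets[[i]], codes)
    M[i, j[!is.na(j)]] <- 1
  }
  M
}

#' Pooled confusion counts over all document-label cells
#'
#' @param gold,pred Indicator matrices of identical shape.
#' @return One-row tibble with columns `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(gold, pred) {
  if (!all(dim(gold) == dim(pred))) {
    stop("gold and prediction matrices differ in shape", call. = FALSE)
  }
  tp <- sum(gold == 1 & pred == 1)
  fp <- sum(gold == 0 & pred == 1)
  fn <- sum(gold == 1 & pred == 0)
  tibble(tp = tp, fp = fp, fn = fn)
}

#' Micro-averaged precision, recall and F1
#'
#' Precision is pooled true positives over all predicted positives; recall
#' is pooled true positives over all actual positives; F1 is their harmonic
#' mean. A zero denominator returns 0 by convention (reachable under
#' extreme label sparsity).
#'
#' @param counts A [confusion_counts()] row (or any list with `tp`, `fp`,
#'   `fn`).
#' @return A numeric scalar.
#' @export
micro_precision <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) 0 else counts$tp / d
}

#' @rdname micro_precision
#' @export
micro_recall <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) 0 else counts$tp / d
}

#' @rdname micro_precision
#' @export
micro_f1 <- function(counts) {
  p <- micro_precision(counts)
  r <- micro_recall(counts)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Micro-averaged AUROC
#'
#' Area under the receiver operating characteristic curve of the flattened
#' per-cell scores against the flattened gold indicators (true-positive
#' rate against false-positive rate, pooled globally). Ties are handled by
#' mid-rank, so constant scores give 0.5.
#'
#' @param gold Indicator matrix (or vector).
#' @param scores Score matrix (or vector) of identical shape.
#' @return AUROC in \code{[0, 1]}.
#' @export
micro_auroc <- function(gold, scores) {
  g <- as.numeric(gold)
  s <- as.numeric(scores)
  if (length(g) != length(s)) {
    stop("gold and score matrices differ in shape", call. = FALSE)
  }
  npos <- sum(g == 1)
  nneg <- sum(g == 0)
  if (npos == 0 || nneg == 0) {
    stop("micro_auroc needs at least one positive and one negative cell",
         call. = FALSE)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[g == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Percentile bootstrap confidence interval for a micro metric
#'
#' Documents (matrix rows) are resampled with replacement; the metric is
#' recomputed on each replicate and the interval is the percentile band at
#' `(1 - level) / 2` on each side. The point estimate is the metric on the
#' full data. A replicate on which the metric is undefined (e.g. no
#' positive cells) is redrawn, with a cap of `10 * n_reps` attempts.
#' Deterministic given the seed.
#'
#' @param metric A function `metric(gold_rows, x_rows)` returning a scalar.
#' @param gold Indicator matrix.
#' @param x Prediction indicator matrix or score matrix, same row order.
#' @param n_reps Bootstrap replicates; default 100.
#' @param level Confidence level; default 0.95.
#' @param seed Integer seed.
#' @return A one-row tibble: `point`, `ci_low`, `ci_high`, `n_reps`.
#' @export
bootstrap_ci <- function(metric, gold, x, n_reps = 100L, level = 0.95,
                         seed = 1L) {
  stopifnot(n_reps >= 1, level > 0, level < 1)
  point <- metric(gold, x)
  n <- nrow(gold)
  vals <- withr::with_seed(seed, {
    out <- numeric(n_reps)
    draws <- 0L
    k <- 0L
    while (k < n_reps) {
      if (draws >= 10L * n_reps) {
        stop("bootstrap: metric undefined on too many replicates",
             call. = FALSE)
      }
      draws <- draws + 1L
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric(gold[idx, , drop = FALSE],
                           x[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
      if (is.finite(v)) {
        k <- k + 1L
        out[k] <- v
      }
    }
    out
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  tibble(point = point, ci_low = q[1], ci_high = q[2],
         n_reps = as.integer(n_reps))
}

#' Evaluate predictions with micro metrics and bootstrap CIs
#'
#' Computes micro precision, recall, F1 and (when scores are supplied)
#' micro-AUROC, each with a document-resampling percentile bootstrap CI.
#'
#' @param gold_sets List of gold code sets per document.
#' @param pred_sets List of predicted code sets per document.
#' @param space A [label_space()].
#' @param scores Optional score matrix (documents x labels) for AUROC.
#' @param n_bootstrap Bootstrap replicates; default 100.
#' @param level Confidence level; default 0.95.
#' @param seed Integer seed.
#' @return A `metrics_report` tibble: one row per metric with `point`,
#'   `ci_low`, `ci_high`.
#' @export
evaluate_predictions <- function(gold_sets, pred_sets, space, scores = NULL,
                                 n_bootstrap = 100L, level = 0.95,
                                 seed = 1L) {
  gold <- label_matrix(gold_sets, space)
  pred <- label_matrix(pred_sets, space)
  fns <- list(
    micro_precision = function(g, p) micro_precision(confusion_counts(g, p)),
    micro_recall    = function(g, p) micro_recall(confusion_counts(g, p)),
    micro_f1        = function(g, p) micro_f1(confusion_counts(g, p))
  )
  rows <- purrr::imap_dfr(fns, function(f, nm) {
    dplyr::mutate(bootstrap_ci(f, gold, pred, n_bootstrap, level, seed),
                  metric = nm, .before = 1)
  })
  if (!is.null(scores)) {
    rows <- dplyr::bind_rows(rows, dplyr::mutate(
      bootstrap_ci(micro_auroc, gold, scores, n_bootstrap, level, seed),
      metric = "micro_auroc", .before = 1))
  }
  structure(rows, class = c("metrics_report", class(rows)),
            n_bootstrap = as.integer(n_bootstrap), level = level,
            seed = as.integer(seed))
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) as_tibble(x)

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- stats::setNames(x$point, x$metric)
  dplyr::bind_cols(as_tibble(as.list(wide)),
                   tibble(n_bootstrap = attr(x, "n_bootstrap"),
                          level = attr(x, "level")))
}

#' Plot a metrics report
#'
#' Point estimates with bootstrap CI error bars, one row per metric.
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "score (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
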