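# Pluggable multilabel text classifier. The desk backend is a bag-of-words
# independent-per-label linear model with sigmoid outputs, trained by
# full-batch Adam on summed per-label binary cross-entropy; it is
# deterministic given (data, config, seed) and runs in seconds at study
# scale. The contextual backend shares the same linear head and trainer but
# takes pooled representations from a user-supplied encoder function,
# matching the contract of transformer pipelines (token truncation, pooled
# output, linear layer, cross-entropy, Adam, early stop).

#' Training configuration
#'
#' @param backend `"DESK_LINEAR"` (deterministic bag-of-words linear
#'   scorers) or `"CONTEXTUAL"` (pooled encoder representation + linear
#'   head; requires `encoder`).
#' @param learning_rate Adam step size. Defaults: 0.1 for the desk backend,
#'   0.00005 for the contextual backend (the value used when fine-tuning
#'   transformer encoders).
#' @param max_epochs Maximum full-batch epochs; default 100.
#' @param early_stop_delta Stop when the monitored loss changes by less
#'   than this for `early_stop_patience` consecutive epochs; default 1e-4.
#' @param early_stop_patience Epochs of sub-delta change tolerated before
#'   stopping; default 10.
#' @param max_tokens Token truncation length for the contextual backend;
#'   default 512.
#' @param l2 L2 penalty on the feature weights (not the bias), the
#'   standard regularizer for one-vs-rest logistic scorers; default 0.001
#'   for the desk backend, 0 for the contextual backend.
#' @param threshold Score cut-off for converting probabilities to code
#'   sets; default 0.5.
#' @param seed Integer seed recorded in provenance and used for any
#'   stochastic component.
#' @param encoder For the contextual backend: a function mapping a
#'   character vector of (truncated) texts to a numeric matrix of pooled
#'   representations, one row per text.
#' @return A `train_config` list.
#' @export
train_config <- function(backend = c("DESK_LINEAR", "CONTEXTUAL"),
                         learning_rate = NULL,
                         max_epochs = 100L,
                         early_stop_delta = 1e-4,
                         early_stop_patience = 10L,
                         max_tokens = 512L,
                         l2 = NULL,
                         threshold = 0.5,
                         seed = 1L,
                         encoder = NULL) {
  backend <- match.arg(backend)
  if (is.null(learning_rate)) {
    learning_rate <- if (backend == "DESK_LINEAR") 0.1 else 5e-5
  }
  if (is.null(l2)) l2 <- if (backend == "DESK_LINEAR") 1e-3 else 0
  stopifnot(threshold > 0, threshold < 1, max_epochs >= 1,
            early_stop_patience >= 1, learning_rate > 0, max_tokens >= 1,
            l2 >= 0)
  structure(list(backend = backend, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_delta = early_stop_delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_tokens = as.integer(max_tokens), l2 = l2,
                 threshold = threshold, seed = as.integer(seed),
                 encoder = encoder),
            class = "train_config")
}

tokenize_text <- function(text) {
  stringr::str_split(stringr::str_squish(text), stringr::fixed(" "))
}

truncate_tokens <- function(text, max_tokens) {
  toks <- tokenize_text(text)
  vapply(toks, function(t) paste(utils::head(t[nzchar(t)], max_tokens),
                                 collapse = " "), character(1))
}

# Binary presence document-term matrix over a fixed vocabulary.
doc_term_matrix <- function(texts, vocab) {
  toks <- tokenize_text(texts)
  ij <- purrr::imap(toks, function(t, i) {
    j <- unique(match(t, vocab))
    j <- j[!is.na(j)]
    cbind(i = rep(i, length(j)), j = j)
  })
  ij <- do.call(rbind, ij)
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(length(texts), length(vocab)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# summed per-label binary cross-entropy, averaged over documents
bce_loss <- function(P, Y) {
  eps <- 1e-9
  -sum(Y * log(P + eps) + (1 - Y) * log(1 - P + eps)) / nrow(Y)
}

# Full-batch Adam on W (features x labels) and bias b. X sparse or dense,
# Y dense 0/1. Returns list(W, b, loss_trace, epochs_run).
# Features with zero support in this phase's data feel no data gradient;
# their weights are kept at the starting point rather than decayed, so a
# warm start retains definition knowledge attached to tokens the
# fine-tuning corpus never shows (a no-op for cold starts from zero).
adam_fit <- function(X, Y, lr, max_epochs, delta, patience, l2 = 0,
                     W0 = NULL, b0 = NULL, X_val = NULL, Y_val = NULL) {
  n <- nrow(X); V <- ncol(X); L <- ncol(Y)
  W <- if (is.null(W0)) matrix(0, V, L) else W0
  b <- if (is.null(b0)) rep(0, L) else b0
  W_start <- W
  unsupported <- which(Matrix::colSums(X) == 0)
  mW <- matrix(0, V, L); vW <- matrix(0, V, L)
  mb <- rep(0, L); vb <- rep(0, L)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- numeric(0)
  still <- 0L
  prev <- NA_real_
  Xt <- Matrix::t(X)
  for (epoch in seq_len(max_epochs)) {
    P <- sigmoid(as.matrix(X %*% W) + rep(b, each = n))
    G <- (P - Y) / n
    gW <- as.matrix(Xt %*% G) + l2 * W
    gb <- colSums(G)
    mW <- beta1 * mW + (1 - beta1) * gW
    vW <- beta2 * vW + (1 - beta2) * gW^2
    mb <- beta1 * mb + (1 - beta1) * gb
    vb <- beta2 * vb + (1 - beta2) * gb^2
    c1 <- 1 - beta1^epoch; c2 <- 1 - beta2^epoch
    W <- W - lr * (mW / c1) / (sqrt(vW / c2) + eps)
    b <- b - lr * (mb / c1) / (sqrt(vb / c2) + eps)
    monitored <- if (!is.null(X_val)) {
      Pv <- sigmoid(as.matrix(X_val %*% W) + rep(b, each = nrow(X_val)))
      bce_loss(Pv, Y_val)
    } else {
      bce_loss(sigmoid(as.matrix(X %*% W) + rep(b, each = n)), Y)
    }
    trace <- c(trace, monitored)
    if (!is.na(prev) && abs(monitored - prev) < delta) {
      still <- still + 1L
      if (still >= patience) break
    } else {
      still <- 0L
    }
    prev <- monitored
  }
  if (length(unsupported) > 0) {
    W[unsupported, ] <- W_start[unsupported, ]
  }
  list(W = W, b = b, loss_trace = trace, epochs_run = length(trace))
}

label_targets <- function(labels, space) {
  out <- matrix(0, length(labels), length(space))
  codes <- as.character(space)
  for (i in seq_along(labels)) {
    j <- match(labels[[i]], codes)
    if (anyNA(j)) {
      stop("label outside label space: ",
           paste(labels[[i]][is.na(j)], collapse = ", "), call. = FALSE)
    }
    out[i, j] <- 1
  }
  out
}

#' Fit a multilabel code classifier
#'
#' Trains independent per-label linear scorers with sigmoid outputs by
#' full-batch Adam on summed per-label binary cross-entropy (the standard
#' multilabel reading of cross-entropy with one-hot label targets).
#' Early stopping monitors the validation loss when `validation` is given,
#' else the training loss: training stops once the loss changes by less
#' than `early_stop_delta` for `early_stop_patience` consecutive epochs.
#' The desk backend is bit-reproducible given (data, config, seed).
#'
#' @param examples Training-example tibble (`doc_id`, `input_text`,
#'   `labels`); all labels must lie in `space`.
#' @param space A [label_space()].
#' @param config A [train_config()].
#' @param validation Optional example tibble monitored for early stopping.
#' @param init Optional fitted model to warm-start from (see
#'   [pretrain_on_definitions()]).
#' @return An `icd_model` object.
#' @export
train_classifier <- function(examples, space, config = train_config(),
                             validation = NULL, init = NULL) {
  if (nrow(examples) == 0) stop("no training examples", call. = FALSE)
  if (!is.null(init) && !identical(as.character(init$space),
                                   as.character(space))) {
    stop("warm-start model has a different label space", call. = FALSE)
  }
  texts <- examples$input_text
  if (config$backend == "CONTEXTUAL") {
    if (is.null(config$encoder)) {
      stop("the contextual backend needs an encoder function in the config",
           call. = FALSE)
    }
    texts <- truncate_tokens(texts, config$max_tokens)
    X <- config$encoder(texts)
    vocab <- NULL
    W0 <- init$W; b0 <- init$b
  } else {
    vocab <- sort(unique(unlist(tokenize_text(texts), use.names = FALSE)))
    vocab <- vocab[nzchar(vocab)]
    if (!is.null(init)) vocab <- sort(unique(c(init$vocab, vocab)))
    if (length(vocab) == 0) stop("no tokens in training text", call. = FALSE)
    X <- doc_term_matrix(texts, vocab)
    W0 <- NULL; b0 <- NULL
    if (!is.null(init)) {
      W0 <- matrix(0, length(vocab), length(space))
      W0[match(init$vocab, vocab), ] <- init$W
      if (isTRUE(init$single_label_task)) {
        # a single-label phase (one code per definition) learns negative
        # between-code evidence that does not hold for multi-code records;
        # only positive phrase-to-code associations are carried over, and
        # the bias is re-estimated under the corpus label prior
        W0 <- pmax(W0, 0)
      }
      b0 <- NULL
    }
  }
  Y <- label_targets(examples$labels, space)
  X_val <- NULL; Y_val <- NULL
  if (!is.null(validation) && nrow(validation) > 0) {
    vtexts <- validation$input_text
    if (config$backend == "CONTEXTUAL") {
      X_val <- config$encoder(truncate_tokens(vtexts, config$max_tokens))
    } else {
      X_val <- doc_term_matrix(vtexts, vocab)
    }
    Y_val <- label_targets(validation$labels, space)
  }
  fitted <- withr::with_seed(config$seed, adam_fit(
    X, Y, config$learning_rate, config$max_epochs,
    config$early_stop_delta, config$early_stop_patience, l2 = config$l2,
    W0 = W0, b0 = b0, X_val = X_val, Y_val = Y_val))
  phases <- c(init$provenance$phases,
              list(list(n_examples = nrow(examples),
                        fingerprint = examples_fingerprint(examples))))
  structure(list(
    backend = config$backend, space = space, vocab = vocab,
    W = fitted$W, b = fitted$b,
    loss_trace = fitted$loss_trace, epochs_run = fitted$epochs_run,
    provenance = list(config = config[setdiff(names(config), "encoder")],
                      phases = phases),
    encoder = if (config$backend == "CONTEXTUAL") config$encoder else NULL
  ), class = "icd_model")
}

examples_fingerprint <- function(examples) {
  key <- paste(examples$doc_id, examples$input_text,
               purrr::map_chr(examples$labels, paste, collapse = ","),
               collapse = "\n")
  sum(utf8ToInt(substr(key, 1, 100000)) *
        (seq_len(min(nchar(key), 100000)) %% 97 + 1)) %% 2^31
}

#' Warm-start a classifier on official code definitions
#'
#' Fits the model on definition pairs (see [build_definition_pairs()])
#' first; the returned model is then passed as `init` to
#' [train_classifier()] to continue on corpus examples (strictly sequential
#' phases). Provenance records both phases.
#'
#' @param defs Definition-pair example tibble.
#' @param space A [label_space()].
#' @param config A [train_config()].
#' @return An `icd_model` usable as a warm start.
#' @export
pretrain_on_definitions <- function(defs, space, config = train_config()) {
  model <- train_classifier(defs, space, config)
  model$single_label_task <- TRUE
  model
}

#' Predict per-label scores
#'
#' @param model A fitted `icd_model`.
#' @param texts Character vector of (preprocessed) input texts.
#' @return A numeric matrix, documents x labels, entries in \code{[0, 1]},
#'   column names the label-space codes.
#' @export
predict_scores <- function(model, texts) {
  L <- length(model$space)
  if (length(texts) == 0) {
    return(matrix(numeric(0), 0, L,
                  dimnames = list(NULL, as.character(model$space))))
  }
  if (model$backend == "CONTEXTUAL") {
    cfg <- model$provenance$config
    X <- model$encoder(truncate_tokens(texts, cfg$max_tokens))
  } else {
    X <- doc_term_matrix(texts, model$vocab)
  }
  P <- sigmoid(as.matrix(X %*% model$W) + rep(model$b, each = length(texts)))
  dimnames(P) <- list(NULL, as.character(model$space))
  P
}

#' Predict code sets by thresholding scores
#'
#' A label is included iff its score is at least `threshold`; predicted
#' sets are monotone shrinking in the threshold.
#'
#' @inheritParams predict_scores
#' @param threshold Probability cut-off; defaults to the fitted config's
#'   threshold.
#' @return A list of character vectors of codes, one per text.
#' @export
predict_codes <- function(model, texts, threshold = NULL) {
  threshold <- threshold %||% model$provenance$config$threshold
  P <- predict_scores(model, texts)
  purrr::map(seq_len(nrow(P)), function(i) {
    as.character(model$space)[P[i, ] >= threshold]
  })
}

#' @export
predict.icd_model <- function(object, texts, type = c("codes", "scores"),
                              threshold = NULL, ...) {
  type <- match.arg(type)
  if (type == "scores") predict_scores(object, texts)
  else predict_codes(object, texts, threshold)
}

#' Save / load a fitted model
#'
#' Persists the label space, config provenance and parameters in a single
#' archive; `load_model(save_model(m))` reproduces predictions bit-exactly
#' for the desk backend. Contextual encoder functions are not serialized.
#'
#' @param model An `icd_model`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  model$encoder <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' @export
print.icd_model <- function(x, ...) {
  cat("<icd_model>", x$backend, "|", length(x$space), "labels |",
      if (is.null(x$vocab)) "encoder features" else
        paste(length(x$vocab), "bag-of-words features"),
      "|", x$epochs_run, "epochs\n")
  invisible(x)
}

#' Tidy a fitted code classifier
#'
#' Long tibble of the strongest feature weights per label.
#'
#' @param x An `icd_model`.
#' @param n_terms Features kept per label (by absolute weight); default 5.
#' @param ... Unused.
#' @return A tibble with columns `code`, `term`, `weight`.
#' @method tidy icd_model
#' @export
tidy.icd_model <- function(x, n_terms = 5, ...) {
  if (is.null(x$vocab)) {
    stop("tidy() needs the bag-of-words desk backend", call. = FALSE)
  }
  purrr::map_dfr(seq_along(x$space), function(j) {
    w <- x$W[, j]
    top <- utils::head(order(-abs(w)), n_terms)
    tibble(code = as.character(x$space)[j], term = x$vocab[top],
           weight = w[top])
  })
}

#' Glance at a fitted code classifier
#'
#' @param x An `icd_model`.
#' @param ... Unused.
#' @return One-row tibble: backend, feature and label counts, epochs run,
#'   final monitored loss, number of training phases.
#' @method glance icd_model
#' @export
glance.icd_model <- function(x, ...) {
  tibble(backend = x$backend,
         n_features = if (is.null(x$vocab)) nrow(x$W) else length(x$vocab),
         n_labels = length(x$space),
         epochs_run = x$epochs_run,
         final_loss = x$loss_trace[length(x$loss_trace)],
         n_phases = length(x$provenance$phases))
}
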