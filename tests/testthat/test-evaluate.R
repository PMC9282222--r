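test_that("confusion counts pool over all document-label cells", {
  sp <- c("a", "b", "c")
  g <- label_matrix(list(c("a", "b"), "c"), sp)
  expect_equal(as.list(confusion_counts(g, g)), list(tp = 3, fp = 0, fn = 0))
  p <- label_matrix(list(c("a", "c"), "c"), sp)
  expect_equal(as.list(confusion_counts(g[1, , drop = FALSE],
                                        p[1, , drop = FALSE])),
               list(tp = 1, fp = 1, fn = 1))
  zero <- label_matrix(list(character(0), character(0)), sp)
  expect_equal(as.list(confusion_counts(g, zero)),
               list(tp = 0, fp = 0, fn = 3))
  expect_error(confusion_counts(g, g[1, , drop = FALSE]), "shape")
})

test_that("micro metrics follow the pooled formulas with zero-denominator conventions", {
  cc <- tibble::tibble(tp = 2, fp = 1, fn = 1)
  expect_equal(micro_precision(cc), 2 / 3)
  expect_equal(micro_recall(cc), 2 / 3)
  expect_equal(micro_f1(cc), 2 / 3)
  perfect <- tibble::tibble(tp = 5, fp = 0, fn = 0)
  expect_equal(c(micro_precision(perfect), micro_recall(perfect),
                 micro_f1(perfect)), c(1, 1, 1))
  degenerate <- tibble::tibble(tp = 0, fp = 3, fn = 2)
  expect_equal(micro_f1(degenerate), 0)
  expect_equal(micro_f1(tibble::tibble(tp = 0, fp = 0, fn = 0)), 0)
})

test_that("micro F1 equals its algebraic form on random counts", {
  withr::with_seed(8, {
    for (i in 1:200) {
      cc <- tibble::tibble(tp = sample(0:50, 1), fp = sample(0:50, 1),
                           fn = sample(0:50, 1))
      alg <- if (2 * cc$tp + cc$fp + cc$fn == 0) 0 else
        2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
      expect_equal(micro_f1(cc), alg, tolerance = 1e-12)
    }
  })
})

pairwise_auroc_oracle <- function(g, s) {
  g <- as.numeric(g); s <- as.numeric(s)
  pos <- s[g == 1]; neg <- s[g == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

test_that("micro AUROC handles perfect ranking, ties and matches the pairwise oracle", {
  g <- c(1, 1, 0, 0)
  expect_equal(micro_auroc(g, c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(micro_auroc(g, rep(0.5, 4)), 0.5)
  expect_error(micro_auroc(c(1, 1), c(0.1, 0.2)), "positive and")
  withr::with_seed(13, {
    for (i in 1:50) {
      g <- rbinom(200, 1, 0.3)
      if (sum(g) == 0 || sum(g) == 200) next
      s <- round(runif(200), 2)  # rounding forces ties
      expect_equal(micro_auroc(g, s), pairwise_auroc_oracle(g, s),
                   tolerance = 1e-12)
    }
  })
})

test_that("micro AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(29, {
    g <- matrix(rbinom(60, 1, 0.4), 10)
    s <- matrix(runif(60), 10)
  })
  a <- micro_auroc(g, s)
  expect_equal(micro_auroc(g, 10 * s - 3), a, tolerance = 1e-12)
  expect_equal(micro_auroc(g, exp(s)), a, tolerance = 1e-12)
  expect_equal(micro_auroc(g, qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6))), a,
               tolerance = 1e-12)
})

test_that("micro AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    g <- rbinom(300, 1, 0.25)
    s <- round(runif(300), 2)
  })
  ref <- as.numeric(suppressMessages(pROC::auc(g, s, direction = "<")))
  expect_equal(micro_auroc(g, s), ref, tolerance = 1e-12)
})

test_that("metrics are invariant to document and label permutations", {
  withr::with_seed(41, {
    g <- matrix(rbinom(80, 1, 0.3), 8)
    p <- matrix(rbinom(80, 1, 0.3), 8)
    s <- matrix(runif(80), 8)
  })
  ri <- sample(8); ci <- sample(10)
  expect_equal(as.list(confusion_counts(g, p)),
               as.list(confusion_counts(g[ri, ci], p[ri, ci])))
  expect_equal(micro_auroc(g, s), micro_auroc(g[ri, ci], s[ri, ci]))
})

test_that("bootstrap CIs are deterministic, degenerate-safe and collapse at n_reps = 1", {
  sp <- c("a", "b")
  g <- label_matrix(list("a", "b", c("a", "b")), sp)
  f1 <- function(gg, pp) micro_f1(confusion_counts(gg, pp))
  # perfect predictions: constant metric across replicates
  ci <- bootstrap_ci(f1, g, g, n_reps = 50, seed = 4)
  expect_equal(c(ci$point, ci$ci_low, ci$ci_high), c(1, 1, 1))
  # same seed twice: identical intervals
  withr::with_seed(77, p <- label_matrix(list("a", "a", "b"), sp))
  c1 <- bootstrap_ci(f1, g, p, n_reps = 40, seed = 9)
  c2 <- bootstrap_ci(f1, g, p, n_reps = 40, seed = 9)
  expect_identical(c1, c2)
  # n_reps = 1: interval collapses to that replicate's value
  c3 <- bootstrap_ci(f1, g, p, n_reps = 1, seed = 2)
  expect_equal(c3$ci_low, c3$ci_high)
})

test_that("evaluate_predictions assembles a metrics report with broom methods", {
  sp <- c("a", "b", "c")
  gold <- list(c("a", "b"), "c", "a")
  pred <- list("a", "c", c("a", "c"))
  withr::with_seed(3, scores <- matrix(runif(9), 3,
                                       dimnames = list(NULL, sp)))
  rep <- evaluate_predictions(gold, pred, sp, scores = scores,
                              n_bootstrap = 30, seed = 11)
  expect_setequal(rep$metric, c("micro_precision", "micro_recall",
                                "micro_f1", "micro_auroc"))
  expect_true(all(rep$point >= 0 & rep$point <= 1))
  expect_true(all(rep$ci_low <= rep$ci_high))
  g <- glance(rep)
  expect_equal(g$n_bootstrap, 30L)
  expect_true(all(c("micro_f1", "micro_auroc") %in% names(g)))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("document bootstrap covers the generating F1 of a binomial-noise predictor", {
  # known truth: flip gold cells into predictions with fixed hit/false rates
  n_docs <- 120; n_labels <- 20
  hit <- 0.8; fa <- 0.05; base <- 0.3
  true_f1 <- local({
    tp <- base * hit; fp <- (1 - base) * fa; fn <- base * (1 - hit)
    2 * tp / (2 * tp + fp + fn)
  })
  f1 <- function(gg, pp) micro_f1(confusion_counts(gg, pp))
  withr::with_seed(55, {
    gold <- matrix(rbinom(n_docs * n_labels, 1, base), n_docs)
    covered <- 0L
    n_outer <- 40
    for (r in seq_len(n_outer)) {
      pred <- matrix(rbinom(n_docs * n_labels, 1,
                            ifelse(gold == 1, hit, fa)), n_docs)
      ci <- bootstrap_ci(f1, gold, pred, n_reps = 400, seed = r)
      if (ci$ci_low <= true_f1 && true_f1 <= ci$ci_high) {
        covered <- covered + 1L
      }
    }
  })
  expect_gte(covered / n_outer, 0.85)
  expect_lte(covered / n_outer, 1.0)
})
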