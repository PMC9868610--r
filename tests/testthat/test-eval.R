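# Brute-force metric oracles, independent of the vectorized implementations.

auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

pr_sweep_oracle <- function(scores, labels, what = c("aupr", "fmax")) {
  what <- match.arg(what)
  n_pos <- sum(labels == 1)
  taus <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(taus))
  for (i in seq_along(taus)) {
    called <- scores >= taus[i]
    prec[i] <- sum(labels[called]) / sum(called)
    rec[i] <- sum(labels[called]) / n_pos
  }
  if (what == "fmax") {
    return(max(ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))))
  }
  sum(diff(c(0, rec)) * prec)
}

test_that("pair-mode splits partition pairs at the requested fraction", {
  labs <- tibble::tibble(gene_a = rep("a", 100),
                         gene_b = sprintf("b%03d", 1:100),
                         label = rep(c(1L, 0L), 50))
  sp <- make_split(labs, "pair", 0.8, seed = 3)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_identical(dplyr::bind_rows(sp$train, sp$test) |> nrow(), 100L)
})

test_that("gene-mode splits have zero endpoint overlap and drop cross pairs", {
  genes <- sprintf("g%02d", 1:20)
  cmb <- t(combn(genes, 2))
  labs <- tibble::tibble(gene_a = cmb[, 1], gene_b = cmb[, 2],
                         label = rbinom(nrow(cmb), 1, 0.2))
  sp <- make_split(labs, "gene", 0.7, seed = 5)
  expect_length(intersect(c(sp$train$gene_a, sp$train$gene_b),
                          c(sp$test$gene_a, sp$test$gene_b)), 0)
  expect_identical(nrow(sp$train) + nrow(sp$test) + sp$n_dropped, nrow(labs))
})

test_that("a 2/2 gene split of K4 drops its four cross pairs", {
  cmb <- t(combn(c("a", "b", "c", "d"), 2))
  labs <- tibble::tibble(gene_a = cmb[, 1], gene_b = cmb[, 2], label = 1L)
  sp <- make_split(labs, "gene", 0.5, seed = 1)
  expect_identical(sp$n_dropped, 4L)
  expect_identical(nrow(sp$train), 1L)
  expect_identical(nrow(sp$test), 1L)
})

test_that("cross-validation folds partition the training pairs", {
  labs <- tibble::tibble(gene_a = letters[1:10], gene_b = LETTERS[1:10],
                         label = rep(0:1, 5))
  folds <- cv_folds(labs, k = 5, seed = 2)
  holdouts <- lapply(folds, `[[`, "holdout")
  expect_true(all(vapply(holdouts, nrow, integer(1)) == 2L))
  all_held <- dplyr::bind_rows(holdouts)
  expect_setequal(paste(all_held$gene_a, all_held$gene_b),
                  paste(labs$gene_a, labs$gene_b))
  sizes <- vapply(cv_folds(labs[1:3, ], 2, seed = 1), function(f) nrow(f$holdout),
                  integer(1))
  expect_setequal(sizes, c(2L, 1L))
  expect_error(cv_folds(labs, 11), "exceeds")
})

test_that("precision at k percent follows the ceiling rule and stable ties", {
  expect_equal(precision_at_percent(c(0.9, 0.8, 0.1, 0.2), c(1, 0, 0, 1), 50), 0.5)
  expect_equal(precision_at_percent(runif(30), rep(1, 30), 17), 1)
  # n = 10, k = 5 -> top set of size ceiling(0.5) = 1
  sc <- c(2, rep(1, 9)); lb <- c(1, rep(0, 9))
  expect_equal(precision_at_percent(sc, lb, 5), 1)
  # k = 100 recovers the overall positive rate
  set.seed(9)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.3)
  expect_equal(precision_at_percent(sc, lb, 100), mean(lb))
})

test_that("f_max matches hand cases and the exhaustive sweep oracle", {
  expect_equal(f_max(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(f_max(c(0.9, 0.6, 0.4), c(1, 1, 0)), 1)
  expect_equal(f_max(rep(0.5, 10), rep(c(1, 0), 5)), 2 * 0.5 / 1.5)
  set.seed(31)
  for (i in 1:10) {
    sc <- sample(round(runif(25), 2))  # ties included
    lb <- rbinom(25, 1, 0.4)
    if (sum(lb) == 0) lb[1] <- 1
    expect_equal(f_max(sc, lb), pr_sweep_oracle(sc, lb, "fmax"), tolerance = 1e-12)
  }
})

test_that("f_max dominates the F-measure at any fixed threshold", {
  set.seed(17)
  sc <- runif(50); lb <- rbinom(50, 1, 0.3); lb[1] <- 1
  fm <- f_max(sc, lb)
  for (tau in seq(0.1, 0.9, by = 0.2)) {
    called <- sc >= tau
    if (!any(called)) next
    p <- sum(lb[called]) / sum(called); r <- sum(lb[called]) / sum(lb)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_gte(fm, f - 1e-12)
  }
})

test_that("roc_auc equals the pairwise oracle, honours ties, rejects one class", {
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(7)
  for (i in 1:10) {
    sc <- sample(round(runif(20), 1))
    lb <- rbinom(20, 1, 0.5)
    if (sum(lb) %in% c(0, 20)) lb[1:2] <- c(0, 1)
    expect_equal(roc_auc(sc, lb), auc_oracle(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(13)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.4); lb[1:2] <- c(0, 1)
  base <- roc_auc(sc, lb)
  expect_equal(roc_auc(exp(sc), lb), base, tolerance = 1e-12)
  expect_equal(roc_auc(100 * sc + 3, lb), base, tolerance = 1e-12)
})

test_that("roc_auc and aupr agree with an independent library implementation", {
  set.seed(23)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.35); lb[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-10)
  expect_equal(aupr(sc, lb), pr_sweep_oracle(sc, lb, "aupr"), tolerance = 1e-12)
})

test_that("the metric panel enforces the gene-mode disjointness contract", {
  preds <- tibble::tibble(score = c(0.9, 0.2, 0.7), label = c(1, 0, 0))
  out <- evaluate_predictions(preds, k = 50)
  expect_equal(out$roc_auc, 1)
  expect_identical(out$n_test, 3L)
  corrupt <- structure(list(mode = "gene",
                            train = tibble::tibble(gene_a = "a", gene_b = "b"),
                            test = tibble::tibble(gene_a = "b", gene_b = "c")),
                       class = "sl_split")
  expect_error(evaluate_predictions(preds, 50, split = corrupt),
               "contract violated")
})
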