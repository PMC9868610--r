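# Evaluation protocol: leave-gene-combination-out ("pair") and
# leave-gene-out ("gene") splits, k-fold partitions of the training pairs,
# and the four ranking metrics (ROC-AUC, AUPR, Precision@k%, F-max).
# Metrics are exact, vectorized formulas; tests check them against
# brute-force oracles.

#' Split labelled pairs into training and test sets
#'
#' In `"pair"` mode (leave-gene-combination-out) pairs are partitioned
#' uniformly at random, so a test pair's genes may occur in training pairs.
#' In `"gene"` mode (leave-gene-out) *genes* are partitioned first; a pair
#' is kept only when both endpoints fall in the same partition, and
#' cross-partition pairs are discarded (logged count), so test-pair genes
#' never occur in any training pair.
#'
#' @param labels Tibble from [label_pairs()].
#' @param mode `"pair"` or `"gene"`.
#' @param train_fraction Fraction of pairs (pair mode) or genes (gene mode)
#'   assigned to training.
#' @param seed Integer seed.
#' @return An `"sl_split"` list: `mode`, `train`, `test` (label tibbles),
#'   `train_genes`, `test_genes` (gene mode), `n_dropped`, `seed`.
#' @export
make_split <- function(labels, mode = c("pair", "gene"), train_fraction = 0.8,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie in (0, 1)")
  }
  set.seed(substream(seed, paste0("split-", mode)))
  n <- nrow(labels)
  if (mode == "pair") {
    n_train <- round(train_fraction * n)
    if (n_train < 1 || n_train >= n) abort("both partitions must be non-empty")
    idx <- sample.int(n, n_train)
    train <- labels[idx, ]
    test <- labels[-idx, ]
    train_genes <- test_genes <- NULL
    n_dropped <- 0L
  } else {
    genes <- sort(unique(c(labels$gene_a, labels$gene_b)))
    n_tr_genes <- round(train_fraction * length(genes))
    if (n_tr_genes < 2 || n_tr_genes > length(genes) - 2) {
      abort("gene-mode split needs at least 2 genes per partition")
    }
    train_genes <- sort(sample(genes, n_tr_genes))
    test_genes <- setdiff(genes, train_genes)
    in_tr <- labels$gene_a %in% train_genes & labels$gene_b %in% train_genes
    in_te <- labels$gene_a %in% test_genes & labels$gene_b %in% test_genes
    n_dropped <- sum(!in_tr & !in_te)
    sl_log(sprintf("gene-mode split: discarded %d cross-partition pair(s)",
                   n_dropped))
    train <- labels[in_tr, ]
    test <- labels[in_te, ]
  }
  for (part in list(train = train, test = test)) {
    if ("label" %in% names(part) && nrow(part) > 0 && sum(part$label) == 0) {
      warn("a split partition has zero positive pairs; metrics will degenerate")
    }
  }
  structure(list(mode = mode, train = train, test = test,
                 train_genes = train_genes, test_genes = test_genes,
                 n_dropped = as.integer(n_dropped), seed = as.integer(seed)),
            class = "sl_split")
}

#' @export
print.sl_split <- function(x, ...) {
  cat(sprintf("<sl_split %s: %d train / %d test pairs, %d dropped>\n",
              x$mode, nrow(x$train), nrow(x$test), x$n_dropped))
  invisible(x)
}

#' k-fold partition of training pairs
#'
#' @param train_pairs Tibble of pairs.
#' @param k Number of folds (>= 2, <= number of pairs).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(fit = tibble, holdout =
#'   tibble)`; the holdouts are disjoint and their union is the input.
#' @export
cv_folds <- function(train_pairs, k = 5L, seed = 1L) {
  n <- nrow(train_pairs)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort(sprintf("k = %d exceeds the %d available pairs", k, n))
  set.seed(substream(seed, "cv"))
  fold_of <- sample(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) {
    list(fit = train_pairs[fold_of != f, ], holdout = train_pairs[fold_of == f, ])
  })
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) == 0) abort("empty score vector")
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
}

#' ROC-AUC by the Mann-Whitney statistic
#'
#' Equals the probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth, both classes present.
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("ROC-AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integral of precision over recall, sweeping thresholds downward
#' through the distinct scores (tied scores enter as one block).
#'
#' @inheritParams roc_auc
#' @return Scalar in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort("AUPR needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)  # threshold blocks
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Precision among the top k percent of predictions
#'
#' Ranks all items by score (descending, stable on ties), keeps the top
#' `m = ceiling(k/100 * n)` and returns the fraction of true positives
#' among them.
#'
#' @inheritParams roc_auc
#' @param k Percent in `(0, 100]`.
#' @return Scalar in `[0, 1]`.
#' @export
precision_at_percent <- function(scores, labels, k = 5) {
  check_scores_labels(scores, labels)
  if (!(k > 0 && k <= 100)) abort("k must lie in (0, 100]")
  m <- ceiling(k / 100 * length(scores))
  top <- order(-scores)[seq_len(m)]  # order() is stable: ties keep input order
  mean(labels[top] == 1)
}

#' Maximum F-measure over all score thresholds
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`) and returns the largest harmonic mean of
#' precision and recall.
#'
#' @inheritParams roc_auc
#' @return Scalar in `(0, 1]`.
#' @export
f_max <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort("F-max needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  pred_pos <- seq_along(y)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_block]; pred_pos <- pred_pos[last_of_block]
  prec <- tp / pred_pos
  rec <- tp / n_pos
  f <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  max(f)
}

#' Evaluate predictions with the full metric panel
#'
#' In gene mode the caller can pass the split to re-assert the zero
#' train/test gene-overlap contract as part of the report pipeline.
#'
#' @param predictions Tibble with columns `score` and `label` (e.g. from
#'   [predict.sl_fit()] joined with truth).
#' @param k Percent for [precision_at_percent()].
#' @param split Optional `"sl_split"`; in gene mode its endpoint
#'   disjointness is re-checked (hard failure on violation).
#' @return One-row tibble: `roc_auc`, `aupr`, `precision_at_k`, `k`,
#'   `f_max`, `n_test`, `positive_rate`.
#' @export
evaluate_predictions <- function(predictions, k = 5, split = NULL) {
  if (!is.null(split) && split$mode == "gene") {
    train_endpoints <- unique(c(split$train$gene_a, split$train$gene_b))
    test_endpoints <- unique(c(split$test$gene_a, split$test$gene_b))
    if (length(intersect(train_endpoints, test_endpoints)) > 0) {
      abort("gene-mode contract violated: train and test pairs share genes")
    }
  }
  s <- predictions$score; y <- predictions$label
  tibble::tibble(
    roc_auc = roc_auc(s, y),
    aupr = aupr(s, y),
    precision_at_k = precision_at_percent(s, y, k),
    k = k,
    f_max = f_max(s, y),
    n_test = length(y),
    positive_rate = mean(y == 1)
  )
}
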