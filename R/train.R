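# Optimization loop: per-epoch balanced negative resampling, full-batch (or
# mini-batch) gradient steps with Adam or plain SGD, early stopping on a
# validation metric (ROC-AUC by default), and a hard instrumented check
# that no forbidden (test) pair ever contributes a gradient or an SL-view
# edge.

# Apply f leaf-wise over parallel nested lists of numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

model_params <- function(state) list(W0 = state$W0, W1 = state$W1, head = state$head)

set_model_params <- function(state, params) {
  state$W0 <- params$W0
  state$W1 <- params$W1
  state$head <- params$head
  state
}

#' Carve a stratified validation holdout from training pairs
#'
#' Samples `val_fraction` of positives and of negatives (at least one
#' each) for early-stopping monitoring.
#'
#' @param labels Training pair tibble with a `label` column.
#' @param val_fraction Fraction in (0, 0.5).
#' @param seed Master seed (the `"val-split"` sub-stream is used).
#' @return `list(fit = , validation = )` row partitions of `labels`.
#' @export
carve_validation <- function(labels, val_fraction = 0.1, seed = 1L) {
  set.seed(substream(seed, "val-split"))
  pos <- which(labels$label == 1); neg <- which(labels$label == 0)
  if (length(pos) < 2 || length(neg) < 2) {
    abort("training needs at least 2 positive and 2 negative pairs")
  }
  val_idx <- c(sample(pos, max(1L, round(val_fraction * length(pos)))),
               sample(neg, max(1L, round(val_fraction * length(neg)))))
  list(fit = labels[-val_idx, ], validation = labels[val_idx, ])
}

#' Balanced per-epoch training sample
#'
#' Returns all training positives plus an equal-count uniform random subset
#' of training negatives; the subset is redrawn on every call so successive
#' epochs see different negatives. With fewer negatives than positives all
#' negatives are used (warned).
#'
#' @param labels Tibble of training pairs with a `label` column.
#' @param seed Optional integer seed; by default the call consumes the
#'   current RNG stream (the trainer seeds it per epoch).
#' @return Row-subset tibble of `labels`.
#' @export
sample_balanced_epoch <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- which(labels$label == 1)
  neg <- which(labels$label == 0)
  if (length(pos) == 0) abort("balanced sampling needs at least one positive pair")
  if (length(neg) < length(pos)) {
    warn(sprintf("only %d negatives for %d positives: using all negatives",
                 length(neg), length(pos)))
    take_neg <- neg
  } else {
    take_neg <- sample(neg, length(pos))
  }
  labels[sort(c(pos, take_neg)), ]
}

assert_no_forbidden <- function(pairs, forbidden_keys, what) {
  if (is.null(forbidden_keys) || nrow(pairs) == 0) return(invisible(NULL))
  hit <- pair_key(pairs$gene_a, pairs$gene_b) %in% forbidden_keys
  if (any(hit)) {
    abort(sprintf("leakage: %d test pair(s) reached %s", sum(hit), what))
  }
  invisible(NULL)
}

view_matrices <- function(views) {
  lapply(views, function(v) if (inherits(v, "sl_view")) v$normalized else v)
}

pairs_to_uv <- function(pairs, universe) {
  u <- gene_index(universe, pairs$gene_a)
  v <- gene_index(universe, pairs$gene_b)
  swap <- u > v
  cbind(ifelse(swap, v, u), ifelse(swap, u, v))
}

#' Train the multi-view model
#'
#' Runs the optimization loop: each epoch redraws a balanced sample of the
#' fitting pairs, takes a gradient step on the binary cross-entropy
#' (full-batch by default), and scores a stratified validation holdout
#' with the configured monitor metric (ROC-AUC by default, AUPR via
#' `monitor = "aupr"`); training stops when the monitor has not improved
#' for `patience` epochs and the weights of the best validation epoch are
#' returned. The run is bitwise reproducible from `cfg$seed`.
#'
#' If `forbidden_pairs` (the test partition) is given, every epoch asserts
#' that no forbidden pair contributes a gradient and that none is an edge
#' of the SL view.
#'
#' @param views List of `"sl_view"` objects (or normalized adjacencies)
#'   sharing one universe; the SL view must be built from training
#'   positives only.
#' @param X N x R node-feature matrix from [build_node_features()].
#' @param labels Training pair tibble (`gene_a`, `gene_b`, `label`).
#' @param cfg [sl_config()].
#' @param universe [gene_universe()]; defaults to the first view's.
#' @param forbidden_pairs Optional tibble of pairs that must never reach
#'   training (hard failure if they do).
#' @param validation Optional tibble of validation pairs (with `label`)
#'   already held out by the caller; when `NULL`, a stratified
#'   `val_fraction` of `labels` is carved out here. The front end
#'   ([fit_multiview_sl()]) holds validation pairs out *before* building
#'   the SL view, so the early-stopping monitor measures generalization to
#'   pairs unseen by both the gradients and the SL adjacency.
#' @return List of class `"sl_train"`: `state` (best-epoch weights),
#'   `report` (`epoch_losses`, `val_metric_history`, `stopped_epoch`,
#'   `best_epoch`, `seed`).
#' @export
train_model <- function(views, X, labels, cfg = sl_config(), universe = NULL,
                        forbidden_pairs = NULL, validation = NULL) {
  if (is.null(universe)) {
    universe <- views[[1]]$universe
    if (is.null(universe)) abort("pass `universe` when views are bare matrices")
  }
  A_hats <- view_matrices(views)
  forbidden_keys <- if (is.null(forbidden_pairs)) NULL else {
    cp <- canonicalize_pairs(forbidden_pairs$gene_a, forbidden_pairs$gene_b)
    pair_key(cp$gene_a, cp$gene_b)
  }
  # SL-view anti-leakage: no test pair may be an SL edge
  for (v in views) {
    if (inherits(v, "sl_view") && identical(v$view_id, "SL") &&
        !is.null(forbidden_keys)) {
      idx <- Matrix::which(Matrix::triu(v$adjacency) != 0, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        edges <- canonicalize_pairs(universe[idx[, 1]], universe[idx[, 2]])
        assert_no_forbidden(edges, forbidden_keys, "the SL view's edges")
      }
    }
  }

  assert_no_forbidden(labels, forbidden_keys, "the training pair set")
  if (!is.null(validation)) {
    assert_no_forbidden(validation, forbidden_keys, "the validation set")
  }
  if (is.null(validation)) {
    carved <- carve_validation(labels, cfg$val_fraction, cfg$seed)
    val <- carved$validation
    fit_pairs <- carved$fit
  } else {
    val <- validation
    fit_pairs <- labels
  }
  if (sum(fit_pairs$label == 1) < 1 || sum(fit_pairs$label == 0) < 1 ||
      sum(val$label == 1) < 1) {
    abort("training needs positives and negatives in both fit and validation sets")
  }
  val_uv <- pairs_to_uv(val, universe)

  state <- init_model(ncol(X), cfg$gcn_dims, cfg$head_dims,
                      seed = substream(cfg$seed, "init"))
  params <- model_params(state)
  opt_m <- tree_map(function(p) p * 0, params)
  opt_v <- tree_map(function(p) p * 0, params)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step_count <- 0L

  epoch_losses <- numeric(0)
  val_history <- numeric(0)
  best_metric <- -Inf
  best_params <- params
  best_epoch <- 0L
  stale <- 0L
  epoch <- 0L

  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    set.seed(substream(cfg$seed, paste0("epoch-", epoch)))
    batch_pairs <- sample_balanced_epoch(fit_pairs)
    assert_no_forbidden(batch_pairs, forbidden_keys, "a gradient update")
    uv <- pairs_to_uv(batch_pairs, universe)
    y <- batch_pairs$label

    chunks <- if (is.null(cfg$batch_size)) list(seq_along(y)) else {
      split(sample(seq_along(y)), ceiling(seq_along(y) / cfg$batch_size))
    }
    epoch_loss <- 0
    state <- set_model_params(state, params)
    for (ch in chunks) {
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- lapply(cfg$head_dims, function(w) {
          matrix(stats::rbinom(length(ch) * w, 1, 1 - cfg$dropout) /
                   (1 - cfg$dropout), length(ch), w)
        })
      }
      fg <- model_loss_grads(A_hats, X, uv[ch, , drop = FALSE], y[ch],
                             state, masks)
      if (!is.finite(fg$loss)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      }
      epoch_loss <- epoch_loss + fg$loss * length(ch)
      grads <- fg$grads
      if (cfg$weight_decay > 0) {
        grads <- tree_map(function(g, p) g + cfg$weight_decay * p, grads, params)
      }
      if (cfg$optimizer == "adam") {
        step_count <- step_count + 1L
        opt_m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, opt_m, grads)
        opt_v <- tree_map(function(v, g) b2 * v + (1 - b2) * g^2, opt_v, grads)
        bc1 <- 1 - b1^step_count; bc2 <- 1 - b2^step_count
        params <- tree_map(function(p, m, v) {
          p - cfg$learning_rate * (m / bc1) / (sqrt(v / bc2) + adam_eps)
        }, params, opt_m, opt_v)
      } else {
        params <- tree_map(function(p, g) p - cfg$learning_rate * g,
                           params, grads)
      }
      state <- set_model_params(state, params)
    }
    epoch_losses <- c(epoch_losses, epoch_loss / length(y))

    val_scores <- model_scores(A_hats, X, val_uv, state)
    val_metric <- if (cfg$monitor == "aupr") aupr(val_scores, val$label) else
      roc_auc(val_scores, val$label)
    val_history <- c(val_history, val_metric)

    if (val_metric > best_metric) {
      best_metric <- val_metric
      best_params <- params
      best_epoch <- epoch
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }

  state <- set_model_params(state, best_params)
  structure(list(
    state = state,
    report = structure(list(epoch_losses = epoch_losses,
                            val_metric_history = val_history,
                            stopped_epoch = epoch,
                            best_epoch = best_epoch,
                            seed = cfg$seed),
                       class = "sl_train_report"),
    universe = universe, config = cfg
  ), class = "sl_train")
}

#' @export
print.sl_train_report <- function(x, ...) {
  cat(sprintf("<sl_train_report: stopped at epoch %d, best val AUPR %.4f at epoch %d>\n",
              x$stopped_epoch,
              if (length(x$val_metric_history)) max(x$val_metric_history) else NA,
              x$best_epoch))
  invisible(x)
}
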