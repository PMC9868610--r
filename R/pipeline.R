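# Front end tying the modules together: label pairs, split, build the five
# views (the SL view from training positives only), build node features,
# train, and score the held-out pairs.

#' Fit the multi-view SL model on a dataset
#'
#' End-to-end fit: labels screened pairs at the configured GI threshold,
#' draws the train/test split (pair or gene mode), rebuilds the SL view
#' from *training* positives only, encodes the requested views, trains with
#' balanced negative resampling and early stopping, and evaluates on the
#' test partition. Test pairs are passed to the trainer as forbidden, so
#' any leakage into gradients or SL edges is a hard failure.
#'
#' @param dataset An `"sl_dataset"` (see [generate_dataset()]) or a list
#'   with fields `genes`, `gi`, `edges`, `node_features`.
#' @param config [sl_config()].
#' @param views Character vector of views to use: any of `"SL"`,
#'   `"PPI_PHYS"`, `"PPI_GEN"`, `"COEXPR"`, `"COESS"`, `"RANDOM"` (an
#'   Erdos-Renyi graph at `random_density`, the ablation baseline).
#' @param split Optional precomputed `"sl_split"`; by default one is drawn
#'   from `config` (`split_mode`, `train_fraction`, `seed`).
#' @param random_density Density of the `"RANDOM"` baseline view.
#' @return List of class `"sl_fit"`: `state`, `report`, `config`,
#'   `universe`, `views` (the fitted `"sl_view"` objects), `split`,
#'   `test_scores` (tibble `gene_a`, `gene_b`, `score`, `label`), `metrics`
#'   (one-row tibble).
#' @export
fit_multiview_sl <- function(dataset, config = sl_config(),
                             views = c("SL", "PPI_PHYS", "PPI_GEN",
                                       "COEXPR", "COESS"),
                             split = NULL, random_density = 0.02) {
  universe <- gene_universe(dataset$genes)
  labels <- label_pairs(dataset$gi, config$sl_threshold)
  if (is.null(split)) {
    split <- make_split(labels, config$split_mode, config$train_fraction,
                        seed = config$seed)
  }

  carved <- carve_validation(split$train, config$val_fraction, config$seed)

  view_objs <- lapply(views, function(vid) {
    if (vid == "SL") {
      # SL edges come from *fitting* positives only: test pairs must never
      # enter the view (anti-leakage), and validation pairs are kept out so
      # the early-stopping monitor rewards generalization, not recall of
      # edges the encoder can already see.
      build_sl_graph(carved$fit, universe)
    } else if (vid == "RANDOM") {
      pairs <- generate_random_view(as.character(universe), random_density,
                                    seed = substream(config$seed, "random-view"))
      view_graph(pairs, universe, "RANDOM")
    } else {
      if (!vid %in% names(dataset$edges)) {
        abort(sprintf("dataset has no edge list for view '%s'", vid))
      }
      view_graph(dataset$edges[[vid]], universe, vid)
    }
  })
  names(view_objs) <- views

  X <- build_node_features(dataset$node_features, universe)
  fit <- train_model(view_objs, X, carved$fit, config, universe,
                     forbidden_pairs = split$test,
                     validation = carved$validation)

  # For test-time scoring the SL view is rebuilt from *all* training
  # positives: the validation holdout only had to stay out of the view
  # while it was steering early stopping. Test pairs remain excluded.
  if ("SL" %in% names(view_objs)) {
    view_objs[["SL"]] <- build_sl_graph(split$train, universe)
  }
  A_hats <- view_matrices(view_objs)
  test_uv <- pairs_to_uv(split$test, universe)
  test_scores <- tibble::tibble(
    gene_a = split$test$gene_a, gene_b = split$test$gene_b,
    score = model_scores(A_hats, X, test_uv, fit$state),
    label = split$test$label
  )
  metrics <- evaluate_predictions(test_scores, k = config$precision_at_percent,
                                  split = split)

  structure(list(state = fit$state, report = fit$report, config = config,
                 universe = universe, views = view_objs, X = X,
                 split = split, test_scores = test_scores, metrics = metrics),
            class = "sl_fit")
}

#' @export
print.sl_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<sl_fit: %s split, views [%s]>\n", x$split$mode,
              paste(names(x$views), collapse = ", ")))
  cat(sprintf("  test: ROC-AUC %.3f | AUPR %.3f | Precision@%g%% %.3f | F-max %.3f (n = %d)\n",
              m$roc_auc, m$aupr, m$k, m$precision_at_k, m$f_max, m$n_test))
  cat(sprintf("  training: best epoch %d of %d\n",
              x$report$best_epoch, x$report$stopped_epoch))
  invisible(x)
}

#' Score gene pairs with a fitted model
#'
#' @param object An `"sl_fit"`.
#' @param pairs Tibble with columns `gene_a`, `gene_b` (a `label` column,
#'   if present, is carried through).
#' @param ... Unused.
#' @return Tibble `gene_a`, `gene_b`, `score` (probability of synthetic
#'   lethality), plus `label` when supplied.
#' @export
predict.sl_fit <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(object$test_scores)
  uv <- pairs_to_uv(pairs, object$universe)
  out <- canonicalize_pairs(pairs$gene_a, pairs$gene_b)
  out$score <- model_scores(view_matrices(object$views), object$X, uv,
                            object$state)
  if ("label" %in% names(pairs)) out$label <- pairs$label
  out
}

#' Tidy per-epoch training history
#'
#' @param x An `"sl_fit"` or `"sl_train"`.
#' @param ... Unused.
#' @return Tibble `epoch`, `train_loss`, `val_metric` (the early-stopping
#'   monitor, ROC-AUC by default).
#' @method tidy sl_fit
#' @export
tidy.sl_fit <- function(x, ...) {
  r <- x$report
  tibble::tibble(epoch = seq_along(r$epoch_losses),
                 train_loss = r$epoch_losses,
                 val_metric = r$val_metric_history)
}

#' @rdname tidy.sl_fit
#' @method tidy sl_train
#' @export
tidy.sl_train <- tidy.sl_fit

#' One-row model summary
#'
#' @param x An `"sl_fit"`.
#' @param ... Unused.
#' @return The test-set metric tibble with training metadata columns.
#' @method glance sl_fit
#' @export
glance.sl_fit <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(best_epoch = x$report$best_epoch,
                                  stopped_epoch = x$report$stopped_epoch,
                                  split_mode = x$split$mode,
                                  n_views = length(x$views),
                                  seed = x$config$seed))
}

#' Plot training history
#'
#' Train loss and the validation monitor metric per epoch, with the
#' selected best epoch marked.
#'
#' @param object An `"sl_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sl_fit
#' @export
autoplot.sl_fit <- function(object, ...) {
  hist <- tidy(object)
  long <- tidyr::pivot_longer(hist, c("train_loss", "val_metric"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$report$best_epoch,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training history (dashed: best validation epoch)") +
    ggplot2::theme_minimal()
}

#' Precision-recall and ROC curves for scored pairs
#'
#' @param predictions Tibble with `score` and `label` columns.
#' @return A ggplot object with the two curves side by side.
#' @export
plot_ranking_curves <- function(predictions) {
  s <- predictions$score; y <- predictions$label
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  n_pos <- sum(y); n_neg <- length(y) - n_pos
  df <- dplyr::bind_rows(
    tibble::tibble(x = tp / n_pos, y = tp / (tp + fp), curve = "precision-recall"),
    tibble::tibble(x = fp / n_neg, y = tp / n_pos, curve = "ROC")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = "recall / false-positive rate",
                  y = "precision / true-positive rate") +
    ggplot2::theme_minimal()
}
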