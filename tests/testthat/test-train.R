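toy_problem <- function(seed = 6) {
  set.seed(seed)
  n <- 5
  A1 <- adj_from_edges(n, list(c(1, 2), c(2, 3), c(4, 5)))
  A2 <- adj_from_edges(n, list(c(1, 3), c(3, 5)))
  list(A_hats = list(normalize_adjacency(A1), normalize_adjacency(A2)),
       X = matrix(rnorm(n * 4), n, 4),
       uv = rbind(c(1, 2), c(2, 4), c(3, 5), c(1, 5), c(2, 5)),
       y = c(1, 0, 1, 0, 1),
       state = init_model(4, c(6L, 4L), c(5L, 4L, 3L), seed = seed))
}

test_that("balanced epoch sampling keeps all positives and matches counts", {
  labs <- tibble::tibble(gene_a = "a", gene_b = sprintf("b%04d", 1:1010),
                         label = c(rep(1L, 10), rep(0L, 1000)))
  set.seed(1)
  b1 <- sample_balanced_epoch(labs)
  expect_identical(nrow(b1), 20L)
  expect_identical(sum(b1$label), 10L)
  expect_true(all(labs$gene_b[labs$label == 1] %in% b1$gene_b))
  b2 <- sample_balanced_epoch(labs)
  expect_false(identical(sort(b1$gene_b[b1$label == 0]),
                         sort(b2$gene_b[b2$label == 0])))
})

test_that("balanced sampling degenerates gracefully with scarce negatives", {
  labs <- tibble::tibble(gene_a = "a", gene_b = sprintf("b%02d", 1:14),
                         label = c(rep(1L, 10), rep(0L, 4)))
  expect_warning(b <- sample_balanced_epoch(labs, seed = 2), "all negatives")
  expect_identical(nrow(b), 14L)
  expect_error(sample_balanced_epoch(dplyr::filter(labs, label == 0)),
               "at least one positive")
})

test_that("analytic gradients match central finite differences on a toy problem", {
  tp <- toy_problem()
  fg <- slview:::model_loss_grads(tp$A_hats, tp$X, tp$uv, tp$y, tp$state)
  h <- 1e-5
  relerr <- function(num, ana) {
    sqrt(sum((num - ana)^2)) / max(sqrt(sum(ana^2)), 1e-8)
  }
  num_grad_matrix <- function(get, set) {
    p <- get(tp$state)
    g <- p * 0
    for (i in seq_along(p)) {
      for (sgn in c(1, -1)) {
        p2 <- p; p2[i] <- p[i] + sgn * h
        l <- slview:::model_loss_grads(tp$A_hats, tp$X, tp$uv, tp$y,
                                       set(tp$state, p2))$loss
        g[i] <- g[i] + sgn * l / (2 * h)
      }
    }
    g
  }
  gW1 <- num_grad_matrix(function(s) s$W1, function(s, p) { s$W1 <- p; s })
  expect_lt(relerr(gW1, fg$grads$W1), 1e-4)
  gW0 <- num_grad_matrix(function(s) s$W0, function(s, p) { s$W0 <- p; s })
  expect_lt(relerr(gW0, fg$grads$W0), 1e-4)
  gH1 <- num_grad_matrix(function(s) s$head[[1]]$W,
                         function(s, p) { s$head[[1]]$W <- p; s })
  expect_lt(relerr(gH1, fg$grads$head[[1]]$W), 1e-4)
  gB4 <- num_grad_matrix(function(s) s$head[[4]]$b,
                         function(s, p) { s$head[[4]]$b <- p; s })
  expect_lt(relerr(gB4, fg$grads$head[[4]]$b), 1e-4)
})

test_that("training is bitwise reproducible from the seed", {
  ds <- small_dataset(seed = 2, n_genes = 80L)
  cfg <- test_recipe(2, max_epochs = 12L, patience = 12L)
  f1 <- fit_multiview_sl(ds, cfg, views = c("SL", "PPI_GEN"))
  f2 <- fit_multiview_sl(ds, cfg, views = c("SL", "PPI_GEN"))
  expect_identical(f1$report$epoch_losses, f2$report$epoch_losses)
  expect_identical(f1$report$val_metric_history, f2$report$val_metric_history)
  expect_identical(f1$test_scores$score, f2$test_scores$score)
})

test_that("training reduces the loss on planted data for most seeds", {
  wins <- 0L
  for (s in 1:5) {
    ds <- small_dataset(seed = s, n_genes = 80L)
    cfg <- test_recipe(s, max_epochs = 10L, patience = 10L)
    f <- fit_multiview_sl(ds, cfg, views = c("SL", "PPI_GEN"))
    losses <- f$report$epoch_losses
    wins <- wins + (losses[10] < losses[1])
    expect_true(all(is.finite(losses)))
  }
  expect_gte(wins, 4L)
})

test_that("forbidden pairs in a gradient batch or the SL view abort training", {
  ds <- small_dataset(seed = 3, n_genes = 60L)
  uni <- gene_universe(ds$genes)
  labs <- label_pairs(ds$gi)
  sp <- make_split(labs, "pair", 0.8, seed = 3)
  X <- build_node_features(ds$node_features, uni)
  cfg <- test_recipe(3, max_epochs = 3L)
  views <- list(build_sl_graph(sp$train, uni))

  # poisoned batch: a test pair smuggled into the training labels
  poisoned <- dplyr::bind_rows(sp$train, sp$test[1, ])
  expect_error(
    train_model(views, X, poisoned, cfg, uni, forbidden_pairs = sp$test),
    "leakage"
  )
  # poisoned view: SL graph built from all labels, test positives included
  test_pos <- sp$test[sp$test$label == 1, ][1, ]
  bad_view <- build_sl_graph(dplyr::bind_rows(sp$train, test_pos), uni)
  expect_error(
    train_model(list(bad_view), X, sp$train, cfg, uni,
                forbidden_pairs = sp$test),
    "leakage"
  )
  # clean inputs train without complaint
  fit <- train_model(views, X, sp$train, cfg, uni, forbidden_pairs = sp$test)
  expect_s3_class(fit, "sl_train")
  expect_identical(fit$report$stopped_epoch, 3L)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  tp <- toy_problem()
  labs <- tibble::tibble(gene_a = c("g1", "g2", "g1", "g2", "g3"),
                         gene_b = c("g2", "g4", "g5", "g5", "g4"),
                         label = c(1L, 0L, 1L, 0L, 1L))
  uni <- gene_universe(sprintf("g%d", 1:5))
  cfg <- sl_config(seed = 1, learning_rate = 1e8, optimizer = "sgd",
                   max_epochs = 50L, val_fraction = 0.4)
  expect_error(
    suppressWarnings(train_model(tp$A_hats, tp$X, labs, cfg, uni)),
    "diverged|non-finite"
  )
})
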