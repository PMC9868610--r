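test_that("SL labelling is strict at the threshold", {
  scores <- tibble::tibble(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                           gi_score = c(-3.5, -3.0, 1.2))
  labs <- label_pairs(scores, threshold = -3)
  expect_identical(labs$label[labs$gene_b == "B"], 1L)   # -3.5 < -3
  expect_identical(labs$label[labs$gene_a == "A" & labs$gene_b == "C"], 0L)  # boundary
  expect_identical(labs$label[labs$gene_a == "B"], 0L)
})

test_that("non-finite GI scores are rejected with a warning, others kept", {
  scores <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"),
                           gi_score = c(NaN, -4))
  expect_warning(labs <- label_pairs(scores), "non-finite")
  expect_identical(nrow(labs), 1L)
  expect_identical(labs$label, 1L)
})

test_that("the SL view contains exactly the positive pairs", {
  uni <- gene_universe(c("A", "B", "C"))
  labs <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("B", "C"),
                         label = c(1L, 0L))
  v <- build_sl_graph(labs, uni)
  expect_equal(as.matrix(v$adjacency), adj_from_edges(3, list(c(1, 2))),
               ignore_attr = TRUE)
  # all-negative labels: empty adjacency, normalization = identity
  v0 <- build_sl_graph(dplyr::mutate(labs, label = 0L), uni)
  expect_equal(as.matrix(v0$normalized), diag(3), ignore_attr = TRUE)
  # triangle of positives
  tri <- tibble::tibble(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                        label = 1L)
  expect_equal(as.matrix(build_sl_graph(tri, uni)$adjacency),
               adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3))),
               ignore_attr = TRUE)
})

test_that("normalization matches the hand-computed two-node path", {
  Ah <- normalize_adjacency(adj_from_edges(2, list(c(1, 2))))
  expect_equal(as.matrix(Ah), matrix(0.5, 2, 2), ignore_attr = TRUE)
})

test_that("normalization of the empty graph is the identity; isolated rows are indicators", {
  expect_equal(as.matrix(normalize_adjacency(matrix(0, 3, 3))), diag(3),
               ignore_attr = TRUE)
  A <- adj_from_edges(3, list(c(1, 2)))  # node 3 isolated
  Ah <- as.matrix(normalize_adjacency(A))
  expect_equal(Ah[3, ], c(0, 0, 1), ignore_attr = TRUE)
})

test_that("k-regular graphs normalize to 1/(k+1) on every edge and the diagonal", {
  rings <- list(
    adj_from_edges(2, list(c(1, 2))),                                  # 1-regular
    adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))),       # 2-regular
    1 - diag(4)                                                        # 3-regular K4
  )
  for (k in 1:3) {
    Ah <- as.matrix(normalize_adjacency(rings[[k]]))
    on_support <- (rings[[k]] + diag(nrow(rings[[k]]))) > 0
    expect_equal(unique(round(Ah[on_support], 12)), 1 / (k + 1))
    expect_true(all(Ah[!on_support] == 0))
  }
})

test_that("normalization rejects asymmetric or self-looped input and bounds eigenvalues", {
  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(normalize_adjacency(bad), "symmetric")
  expect_error(normalize_adjacency(diag(2)), "zero diagonal")
  set.seed(11)
  for (i in 1:5) {
    n <- 8
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    Ah <- as.matrix(normalize_adjacency(A))
    expect_equal(Ah, t(Ah))
    ev <- eigen(Ah, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-12 & ev <= 1 + 1e-12))
    # sparsity pattern equals pattern of A + I
    expect_identical(Ah != 0, (A + diag(n)) != 0)
  }
})

test_that("correlation graph connects near-identical profiles and skips constants", {
  set.seed(5)
  base <- rnorm(10)
  prof <- rbind(g1 = base + rnorm(10, sd = 1e-4),
                g2 = base + rnorm(10, sd = 1e-4),
                g3 = rep(2, 10))
  expect_warning(v <- build_correlation_graph(prof, alpha = 0.01), "constant")
  A <- as.matrix(v$adjacency)
  expect_identical(A[1, 2], 1)
  expect_true(all(A[3, ] == 0))
  expect_error(build_correlation_graph(prof[, 1:2], 0.01), "at least 3 samples")
})

test_that("correlation-graph edge rate under the null is close to alpha", {
  # 2,000 independent gaussian pair profiles, 10 samples each, fixed seed
  set.seed(91)
  n_pairs <- 2000
  prof_a <- matrix(rnorm(n_pairs * 10), n_pairs)
  prof_b <- matrix(rnorm(n_pairs * 10), n_pairs)
  r <- sapply(seq_len(n_pairs), function(i) cor(prof_a[i, ], prof_b[i, ]))
  tt <- abs(r) * sqrt(8 / (1 - r^2))
  hits <- mean(2 * pt(tt, df = 8, lower.tail = FALSE) < 0.01)
  se <- sqrt(0.01 * 0.99 / n_pairs)
  expect_lt(abs(hits - 0.01), 3 * se)
})

test_that("node features are z-scored, mutation binarized, constants guarded", {
  raw <- tibble::tibble(
    gene = c("a", "b", "c"),
    expression = c(1, 2, 6),
    copy_number = c(4, 4, 4),
    mutation = c(0, 2, 0),
    essentiality = c(-1, NA, 1)
  )
  expect_warning(X <- build_node_features(raw), "constant copy_number")
  expect_equal(mean(X[, "expression"]), 0, tolerance = 1e-6)
  expect_equal(sd(X[, "expression"]), 1, tolerance = 1e-6)
  expect_identical(unname(X[, "mutation"]), c(0, 1, 0))
  expect_identical(unname(X[, "copy_number"]), c(0, 0, 0))
  # NA essentiality mean-imputed to 0 before z-scoring
  expect_equal(unname(X[2, "essentiality"]), 0)
  expect_error(build_node_features(raw[, -2]), "expression")
})

test_that("node features follow the universe ordering", {
  raw <- tibble::tibble(gene = c("b", "a"), expression = c(1, 2),
                        copy_number = c(1, 2), mutation = c(1, 0),
                        essentiality = c(1, 2))
  X <- build_node_features(raw, universe = gene_universe(c("a", "b")))
  expect_identical(rownames(X), c("a", "b"))
  expect_identical(unname(X[, "mutation"]), c(0, 1))
})
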