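# Construction of the five network views over a shared gene universe and of
# the 4-column node-feature matrix. Every view is an unweighted, symmetric,
# zero-diagonal adjacency plus its self-loop symmetric normalization
# D^(-1/2) (A + I) D^(-1/2); genes missing from a source network keep their
# universe row with degree 0 (a self-loop-only normalized row) rather than
# being dropped.

view_ids <- c("SL", "PPI_PHYS", "PPI_GEN", "COEXPR", "COESS")

#' Label gene pairs from genetic-interaction scores
#'
#' A screened pair is synthetic lethal iff its GI score is strictly below
#' the threshold (default -3); boundary scores are negatives. All screened
#' pairs are retained, labelled 0/1; records with a non-finite score are
#' rejected with a warning.
#'
#' @param scores Tibble `gene_a`, `gene_b`, `gi_score` (see
#'   [read_gi_table()]).
#' @param threshold Finite labelling threshold.
#' @return Tibble `gene_a`, `gene_b`, `gi_score`, `label` with canonical
#'   (min, max) pair order.
#' @export
label_pairs <- function(scores, threshold = -3) {
  if (!is.finite(threshold)) abort("threshold must be finite")
  bad <- !is.finite(scores$gi_score)
  if (any(bad)) {
    warn(sprintf("rejected %d record(s) with non-finite GI score", sum(bad)))
    scores <- scores[!bad, ]
  }
  out <- canonicalize_pairs(scores$gene_a, scores$gene_b)
  out$gi_score <- scores$gi_score
  out$label <- as.integer(scores$gi_score < threshold)
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' Symmetric self-loop normalization of an adjacency matrix
#'
#' Returns `D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal degree
#' matrix of `A + I`. Every eigenvalue of the result lies in `[-1, 1]`; an
#' isolated node's row is its own self-loop indicator.
#'
#' @param A Symmetric binary adjacency with zero diagonal (dense or
#'   `Matrix` sparse).
#' @return A sparse symmetric `dgCMatrix`.
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A) || !Matrix::isSymmetric(A)) {
    abort("adjacency must be a symmetric square matrix")
  }
  if (any(Matrix::diag(A) != 0)) abort("adjacency must have a zero diagonal")
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  d_inv_sqrt <- 1 / sqrt(Matrix::rowSums(At))
  Dh <- Matrix::Diagonal(n, d_inv_sqrt)
  methods::as(methods::as(Dh %*% At %*% Dh, "generalMatrix"), "CsparseMatrix")
}

adjacency_from_pairs <- function(pairs, universe) {
  n <- length(universe)
  if (nrow(pairs) == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  }
  i <- gene_index(universe, pairs$gene_a)
  j <- gene_index(universe, pairs$gene_b)
  if (any(i == j)) abort("self-edges are not allowed in a view adjacency")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  A@x <- rep(1, length(A@x))  # duplicate-tolerant: binary adjacency
  A
}

#' Construct a network view over the universe
#'
#' Bundles a view's binary adjacency and its normalized form, both indexed
#' by the shared universe ordering.
#'
#' @param pairs Tibble `gene_a`, `gene_b` of edges (restricted to the
#'   universe).
#' @param universe [gene_universe()].
#' @param view_id One of `"SL"`, `"PPI_PHYS"`, `"PPI_GEN"`, `"COEXPR"`,
#'   `"COESS"`, or `"RANDOM"` for baselines.
#' @return An `"sl_view"` list: `view_id`, `universe`, `adjacency`,
#'   `normalized`, `n_edges`.
#' @export
view_graph <- function(pairs, universe, view_id = "SL") {
  A <- adjacency_from_pairs(pairs, universe)
  structure(list(view_id = view_id, universe = universe, adjacency = A,
                 normalized = normalize_adjacency(A),
                 n_edges = as.integer(Matrix::nnzero(A) / 2)),
            class = "sl_view")
}

#' @export
print.sl_view <- function(x, ...) {
  cat(sprintf("<sl_view %s: %d genes, %d edges>\n",
              x$view_id, length(x$universe), x$n_edges))
  invisible(x)
}

#' Build the cell-specific SL view from labelled pairs
#'
#' An edge connects each pair labelled SL. To avoid label leakage the
#' caller must pass *training* pairs only — the fitting front end
#' ([fit_multiview_sl()]) rebuilds this view from the training partition of
#' every split and asserts that no test pair contributes an edge.
#'
#' @param labels Output of [label_pairs()] (training partition).
#' @param universe [gene_universe()].
#' @return An `"sl_view"` with `view_id = "SL"`.
#' @export
build_sl_graph <- function(labels, universe) {
  pos <- labels[labels$label == 1, c("gene_a", "gene_b")]
  view_graph(pos, universe, "SL")
}

#' Build a correlation network from gene profiles
#'
#' Connects two genes when the two-sided p-value of their Pearson
#' correlation across samples falls below `alpha`. The p-value uses the
#' exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom; correlations of either sign qualify and no
#' multiple-testing correction is applied. Constant profiles have undefined
#' correlation and yield no edges (warned once).
#'
#' @param profiles Numeric matrix, genes in rows (row names = identifiers),
#'   samples in columns; at least 3 samples.
#' @param alpha Significance level in (0, 1), default 0.01.
#' @param universe Optional [gene_universe()]; defaults to the profile row
#'   names.
#' @param view_id View tag, `"COEXPR"` or `"COESS"`.
#' @return An `"sl_view"`.
#' @export
build_correlation_graph <- function(profiles, alpha = 0.01, universe = NULL,
                                    view_id = "COEXPR") {
  n_samples <- ncol(profiles)
  if (n_samples < 3) abort("correlation network needs at least 3 samples per gene")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  if (is.null(rownames(profiles))) abort("profiles must carry gene row names")
  if (is.null(universe)) universe <- gene_universe(rownames(profiles))

  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warn(sprintf("%d constant profile(s): undefined correlation, no edges",
                 sum(sds == 0 | is.na(sds))))
  }
  r <- suppressWarnings(stats::cor(base::t(profiles)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  # exact two-sided p from the t distribution; |r| = 1 maps to p = 0
  r_cl <- pmin(pmax(r, -1), 1)
  tt <- abs(r_cl) * sqrt((n_samples - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n_samples - 2, lower.tail = FALSE)
  sig <- p < alpha
  sig[lower.tri(sig, diag = TRUE)] <- FALSE
  idx <- which(sig, arr.ind = TRUE)
  genes <- rownames(profiles)
  pairs <- canonicalize_pairs(genes[idx[, 1]], genes[idx[, 2]])
  view_graph(pairs, universe, view_id)
}

#' Build the node-feature matrix
#'
#' Produces the N x 4 per-gene omics feature matrix: expression, copy
#' number and essentiality are mean-imputed (logged count) and z-scored
#' over genes; the mutation column is binarized (any non-zero value maps to
#' 1, missing to 0). A zero-variance continuous column z-scores to all
#' zeros with a warning.
#'
#' @param raw Matrix or data frame, genes in rows (row names or a `gene`
#'   column), with columns `expression`, `copy_number`, `mutation`,
#'   `essentiality`.
#' @param universe Optional [gene_universe()] fixing row order; defaults to
#'   the input row order.
#' @return Numeric matrix N x 4 with gene row names, class
#'   `"sl_node_features"` attribute-free (plain matrix).
#' @export
build_node_features <- function(raw, universe = NULL) {
  feature_names <- c("expression", "copy_number", "mutation", "essentiality")
  if (is.data.frame(raw)) {
    if ("gene" %in% names(raw)) {
      rn <- as.character(raw$gene)
      raw <- as.matrix(raw[setdiff(names(raw), "gene")])
      rownames(raw) <- rn
    } else {
      raw <- as.matrix(raw)
    }
  }
  missing_cols <- setdiff(feature_names, colnames(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing node-feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.null(rownames(raw))) abort("node features must carry gene row names")
  X <- raw[, feature_names, drop = FALSE]
  if (!is.null(universe)) {
    idx <- match(universe, rownames(X))
    if (anyNA(idx)) {
      abort(sprintf("node features missing for gene(s): %s",
                    paste(universe[is.na(idx)], collapse = ", ")))
    }
    X <- X[idx, , drop = FALSE]
  }

  n_missing <- sum(is.na(X))
  if (n_missing > 0) sl_log(sprintf("imputing %d missing node-feature cell(s)", n_missing))

  zscore <- function(v, name) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warn(sprintf("constant %s column: z-score set to zeros", name))
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  out <- X
  for (nm in c("expression", "copy_number", "essentiality")) {
    out[, nm] <- zscore(X[, nm], nm)
  }
  mut <- X[, "mutation"]
  mut[is.na(mut)] <- 0
  out[, "mutation"] <- as.numeric(mut != 0)
  storage.mode(out) <- "double"
  out
}
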