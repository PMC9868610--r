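# Readers and writers for the plain-text formats the pipeline consumes:
# 2-column TSV edge lists, 3-column genetic-interaction (GI) score tables,
# labelled CSV/TSV matrices, and a YAML run configuration. Contracts are
# strict (fail closed): malformed lines error with their line number rather
# than being silently coerced.

#' Construct a gene universe
#'
#' The universe is the ordered, shared node set of all five network views
#' and of the node-feature matrix: row `i` of every normalized adjacency and
#' of the feature matrix refers to `genes[i]`.
#'
#' @param genes Character vector of unique gene identifiers (opaque,
#'   case-sensitive strings; no symbol mapping is attempted).
#' @return A character vector of class `"sl_universe"`.
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) < 2) abort("a gene universe needs at least 2 genes")
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene identifiers in universe: %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (any(is.na(genes) | genes == "")) abort("empty or NA gene identifier")
  structure(genes, class = c("sl_universe", "character"))
}

#' Map gene identifiers to universe indices
#'
#' @param universe An [gene_universe()] object (or plain character vector).
#' @param genes Identifiers to look up.
#' @return Integer indices in `[1, N]`; errors on unknown genes.
#' @export
gene_index <- function(universe, genes) {
  idx <- match(genes, universe)
  if (anyNA(idx)) {
    abort(sprintf("genes not in universe: %s",
                  paste(unique(genes[is.na(idx)]), collapse = ", ")))
  }
  idx
}

read_delim_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # tolerate Windows line endings; readers must be dialect-independent
  sub("\r$", "", lines)
}

#' Read a two-column edge list
#'
#' Reads a TSV of gene pairs, canonicalizes each pair as (min, max) by
#' lexicographic order, drops self-edges (with a warning) and duplicate
#' pairs, and optionally restricts to a universe (dropped pairs are logged).
#' A third column, if present, is treated as an ignored edge weight.
#'
#' @param path TSV file path, one edge per line.
#' @param universe Optional [gene_universe()]; pairs with a gene outside it
#'   are dropped with a logged count.
#' @param header Logical flag: does row 1 hold column names? Header presence
#'   is declared, never sniffed.
#' @return A tibble with columns `gene_a`, `gene_b` (canonical order).
#' @export
read_edge_list <- function(path, universe = NULL, header = FALSE) {
  lines <- read_delim_lines(path)
  if (header) lines <- lines[-1]
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep) + if (header) 1L else 0L
  lines <- lines[keep]
  if (length(lines) == 0) abort(sprintf("empty edge list: %s", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("malformed edge list %s: fewer than 2 columns at line %d",
                  path, line_no[which(nf < 2)[1]]))
  }
  if (any(nf >= 3)) {
    warn(sprintf("%s: third column present; edge weights are ignored", path))
  }
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)

  self <- a == b
  if (any(self)) {
    warn(sprintf("%s: dropped %d self-edge(s)", path, sum(self)))
    a <- a[!self]; b <- b[!self]
  }
  pairs <- canonicalize_pairs(a, b)
  pairs <- dplyr::distinct(pairs)

  if (!is.null(universe)) {
    inside <- pairs$gene_a %in% universe & pairs$gene_b %in% universe
    if (any(!inside)) {
      sl_log(sprintf("%s: dropped %d pair(s) outside the gene universe",
                     path, sum(!inside)))
      pairs <- pairs[inside, ]
    }
  }
  dplyr::arrange(pairs, .data$gene_a, .data$gene_b)
}

#' Write a two-column edge list
#'
#' Inverse of [read_edge_list()]: writing then reading returns the identical
#' canonical pair set.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param path Output TSV path (no header).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(pairs, path) {
  pairs <- canonicalize_pairs(pairs$gene_a, pairs$gene_b)
  pairs <- dplyr::arrange(dplyr::distinct(pairs), .data$gene_a, .data$gene_b)
  writeLines(paste(pairs$gene_a, pairs$gene_b, sep = "\t"), path)
  invisible(path)
}

#' Read a labelled numeric matrix
#'
#' CSV or TSV with a header row of column labels and a first column of row
#' labels (genes). Cells that read `NA` or are empty are flagged missing
#' (`NA` in the returned matrix); any other non-numeric cell, ragged row, or
#' duplicated row label is an error.
#'
#' @param path File path; delimiter is comma for `.csv`, tab otherwise, or
#'   set `delim` explicitly.
#' @param delim Optional delimiter override.
#' @return A numeric matrix with `dimnames = list(row_ids, col_ids)`.
#' @export
read_matrix <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- read_delim_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) abort(sprintf("matrix file %s needs a header and data rows", path))
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  # header may or may not carry a stub cell for the row-label column
  ncol_body <- lengths(body)
  if (length(unique(ncol_body)) != 1) {
    bad <- which(ncol_body != ncol_body[1])[1] + 1L
    abort(sprintf("ragged matrix %s: row at line %d has %d fields, expected %d",
                  path, bad, ncol_body[bad - 1L], ncol_body[1]))
  }
  p <- ncol_body[1] - 1L
  col_ids <- if (length(header) == p + 1L) header[-1] else header
  if (length(col_ids) != p) {
    abort(sprintf("matrix %s: header has %d labels for %d data columns",
                  path, length(col_ids), p))
  }
  row_ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(row_ids)) {
    abort(sprintf("matrix %s: duplicated row label(s): %s", path,
                  paste(unique(row_ids[duplicated(row_ids)]), collapse = ", ")))
  }
  cells <- vapply(body, function(f) f[-1], character(p))
  cells <- if (p == 1) matrix(cells, ncol = 1) else Matrix::t(cells)
  vals <- suppressWarnings(as.numeric(cells))
  bad <- is.na(vals) & !(cells %in% c("NA", "NaN", "", "nan"))
  if (any(bad)) {
    abort(sprintf("matrix %s: non-numeric cell '%s'", path, cells[which(bad)[1]]))
  }
  m <- matrix(vals, nrow = length(row_ids), ncol = p,
              dimnames = list(row_ids, col_ids))
  if (anyNA(m)) sl_log(sprintf("%s: %d missing cell(s) flagged", path, sum(is.na(m))))
  m
}

#' Read a genetic-interaction score table
#'
#' Three-column TSV `gene_a`, `gene_b`, `gi_score` from a combinatorial
#' knockdown screen. Pairs are canonicalized; self-pairs and duplicated
#' unordered pairs are errors (the screen measures each combination once).
#'
#' @param path TSV path.
#' @param header Logical; is row 1 a header?
#' @return Tibble `gene_a`, `gene_b`, `gi_score`.
#' @export
read_gi_table <- function(path, header = FALSE) {
  lines <- read_delim_lines(path)
  if (header) lines <- lines[-1]
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) abort(sprintf("empty GI table: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    abort(sprintf("malformed GI table %s: expected 3 columns at line %d",
                  path, which(nf != 3)[1] + if (header) 1L else 0L))
  }
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (any(a == b)) {
    abort(sprintf("GI table %s: self-pair at line %d", path, which(a == b)[1]))
  }
  out <- canonicalize_pairs(a, b)
  out$gi_score <- s
  if (anyDuplicated(pair_key(out$gene_a, out$gene_b))) {
    abort(sprintf("GI table %s: duplicated unordered pair(s)", path))
  }
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

config_fields <- c("sl_threshold", "corr_alpha", "gcn_dims", "head_dims",
                   "learning_rate", "max_epochs", "patience", "split_mode",
                   "train_fraction", "cv_folds", "precision_at_percent",
                   "seed", "optimizer", "val_fraction", "dropout",
                   "weight_decay", "batch_size", "monitor")

#' Run configuration
#'
#' Collects every tunable of the pipeline with validated defaults: the SL
#' labelling threshold on GI scores, the correlation-network significance
#' level, the architecture (two graph-convolution widths and three head
#' widths), optimizer settings, and the split protocol.
#'
#' @param sl_threshold GI score threshold; pairs with score strictly below
#'   it are labelled SL. Default -3.
#' @param corr_alpha Two-sided p-value cut-off for correlation-network
#'   edges. Default 0.01.
#' @param gcn_dims Widths of the two shared graph-convolution layers
#'   (default `c(128, 64)`; the second is the embedding dimension).
#' @param head_dims Widths of the three hidden layers of the prediction
#'   head (default `c(64, 32, 16)`).
#' @param learning_rate Optimizer step size (default 1e-4).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without improvement
#'   of validation AUPR.
#' @param split_mode `"pair"` (leave-gene-combination-out) or `"gene"`
#'   (leave-gene-out).
#' @param train_fraction Fraction of pairs (or genes, in gene mode)
#'   assigned to training.
#' @param cv_folds Folds for cross-validation utilities.
#' @param precision_at_percent `k` of the Precision at k percent metric.
#' @param seed Non-negative master seed; all randomness derives from it.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param val_fraction Fraction of training pairs held out (stratified by
#'   label) to monitor early stopping.
#' @param monitor Validation metric steering early stopping: `"roc_auc"`
#'   (default; stable at the small positive counts a 10% holdout of a
#'   sparse screen yields) or `"aupr"`.
#' @param dropout,weight_decay Regularisation knobs, both 0 by default.
#' @param batch_size Mini-batch size; `NULL` (default) trains full-batch on
#'   the balanced epoch sample.
#' @return A list of class `"sl_config"`.
#' @export
sl_config <- function(sl_threshold = -3, corr_alpha = 0.01,
                      gcn_dims = c(128L, 64L), head_dims = c(64L, 32L, 16L),
                      learning_rate = 1e-4, max_epochs = 200L, patience = 20L,
                      split_mode = "pair", train_fraction = 0.8,
                      cv_folds = 5L, precision_at_percent = 5, seed = 1L,
                      optimizer = "adam", val_fraction = 0.1, dropout = 0,
                      weight_decay = 0, batch_size = NULL,
                      monitor = "roc_auc") {
  cfg <- list(
    sl_threshold = as.numeric(sl_threshold), corr_alpha = as.numeric(corr_alpha),
    gcn_dims = as.integer(gcn_dims), head_dims = as.integer(head_dims),
    learning_rate = as.numeric(learning_rate), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), split_mode = split_mode,
    train_fraction = as.numeric(train_fraction), cv_folds = as.integer(cv_folds),
    precision_at_percent = as.numeric(precision_at_percent),
    seed = as.integer(seed), optimizer = optimizer,
    val_fraction = as.numeric(val_fraction), dropout = as.numeric(dropout),
    weight_decay = as.numeric(weight_decay),
    batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
    monitor = monitor
  )
  validate_config(cfg)
  structure(cfg, class = "sl_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) abort(sprintf("invalid config value for '%s': %s", key, msg))
  }
  chk(is.finite(cfg$sl_threshold), "sl_threshold", "must be finite")
  chk(cfg$corr_alpha > 0 && cfg$corr_alpha < 1, "corr_alpha", "must lie in (0, 1)")
  chk(length(cfg$gcn_dims) == 2 && all(cfg$gcn_dims > 0), "gcn_dims",
      "must be two positive integers")
  chk(length(cfg$head_dims) == 3 && all(cfg$head_dims > 0), "head_dims",
      "must be three positive integers")
  chk(cfg$learning_rate > 0, "learning_rate", "must be positive")
  chk(cfg$max_epochs >= 1, "max_epochs", "must be a positive integer")
  chk(cfg$patience >= 1, "patience", "must be a positive integer")
  chk(cfg$split_mode %in% c("pair", "gene"), "split_mode",
      "must be 'pair' or 'gene'")
  chk(cfg$train_fraction > 0 && cfg$train_fraction < 1, "train_fraction",
      "must lie in (0, 1)")
  chk(cfg$cv_folds >= 2, "cv_folds", "must be at least 2")
  chk(cfg$precision_at_percent > 0 && cfg$precision_at_percent <= 100,
      "precision_at_percent", "must lie in (0, 100]")
  chk(cfg$seed >= 0, "seed", "must be non-negative")
  chk(cfg$optimizer %in% c("adam", "sgd"), "optimizer", "must be 'adam' or 'sgd'")
  chk(cfg$monitor %in% c("roc_auc", "aupr"), "monitor",
      "must be 'roc_auc' or 'aupr'")
  chk(cfg$val_fraction > 0 && cfg$val_fraction < 0.5, "val_fraction",
      "must lie in (0, 0.5)")
  chk(cfg$dropout >= 0 && cfg$dropout < 1, "dropout", "must lie in [0, 1)")
  chk(cfg$weight_decay >= 0, "weight_decay", "must be non-negative")
  if (!is.null(cfg$batch_size)) {
    chk(cfg$batch_size >= 1, "batch_size", "must be a positive integer")
  }
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys fail closed; absent keys take the defaults of
#' [sl_config()].
#'
#' @param path YAML key-value file.
#' @return An `"sl_config"` object.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), config_fields)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(sl_config, vals)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a binary weights blob (`<stem>.rds`) plus a sidecar JSON
#' (`<stem>.json`) holding the config, a hash of the gene universe, the seed
#' and the per-epoch metric history, so a run is auditable without loading
#' the blob.
#'
#' @param fit A fitted model from [fit_multiview_sl()] or [train_model()].
#' @param stem Path stem (no extension).
#' @return `stem`, invisibly.
#' @export
save_checkpoint <- function(fit, stem) {
  saveRDS(fit, paste0(stem, ".rds"))
  report <- fit$report
  side <- list(
    config = unclass(fit$config),
    universe_hash = universe_hash(fit$universe),
    n_genes = length(fit$universe),
    seed = report$seed,
    best_epoch = report$best_epoch,
    stopped_epoch = report$stopped_epoch,
    epoch_losses = report$epoch_losses,
    val_metric_history = report$val_metric_history
  )
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(stem) readRDS(paste0(stem, ".rds"))

universe_hash <- function(universe) {
  codes <- utf8ToInt(paste(universe, collapse = "\n"))
  sprintf("%d-%d", length(universe),
          sum(codes * (seq_along(codes) %% 97 + 1)) %% 2147483647)
}
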