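# Synthetic datasets with the statistical structure the method assumes:
# latent gene factors drive a pairwise lethality propensity; thresholding
# calibrated GI scores at -3 yields a sparse positive class (~1.5% of
# pairs, the regime of a large leukemia-line screen, at desk scale); each
# network view connects
# pairs with probability increasing in the planted propensity at a tunable
# informativeness (0 = pure Erdos-Renyi); expression is generated
# independent of the SL structure while gene-level essentiality is planted
# with a weak negative correlation to SL-partner count.

#' Synthetic dataset configuration
#'
#' Defaults mirror the regime of a ~500-gene double-knockdown screen at
#' desk scale: a few hundred genes, ~1.5% positive pairs, five partially
#' overlapping views, and a -0.19 essentiality/SL-degree correlation.
#'
#' @param n_genes Number of genes (default 300).
#' @param n_samples Profile columns per gene (default 50).
#' @param latent_dim Latent factor dimension (default 8).
#' @param positive_rate Target fraction of SL pairs (default 0.015).
#' @param view_informativeness Named vector in `[0, 1]` per view; 0 gives a
#'   pure Erdos-Renyi view. The SL view is informative by construction.
#' @param view_density Named expected edge density per non-SL view.
#' @param missing_gene_fraction Named fraction of genes deleted (degree 0)
#'   per view; the SL screen covers every gene, so its default is 0.
#' @param ess_sl_correlation Planted Pearson correlation between gene-level
#'   essentiality and SL-partner count (default -0.19).
#' @param gi_noise_sd Noise sd added to the standardized propensity before
#'   GI-score calibration (default 0.35).
#' @param ess_noise_sd Within-gene sd of the essentiality profiles.
#' @param mutation_rate Bernoulli rate of the binary mutation feature.
#' @param propensity_steepness Logistic steepness of the edge-probability
#'   mechanism.
#' @param seed Master seed.
#' @return List of class `"sl_synth_config"`.
#' @export
synth_config <- function(n_genes = 300L, n_samples = 50L, latent_dim = 8L,
                         positive_rate = 0.015,
                         view_informativeness = c(SL = 1, PPI_PHYS = 0.3,
                                                  PPI_GEN = 0.6, COEXPR = 0,
                                                  COESS = 0.5),
                         view_density = c(PPI_PHYS = 0.02, PPI_GEN = 0.02,
                                          COEXPR = 0.02, COESS = 0.02),
                         missing_gene_fraction = c(SL = 0, PPI_PHYS = 0.2,
                                                   PPI_GEN = 0.2, COEXPR = 0.2,
                                                   COESS = 0.2),
                         ess_sl_correlation = -0.19, gi_noise_sd = 0.35,
                         ess_noise_sd = 0.5, mutation_rate = 0.1,
                         propensity_steepness = 10, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              latent_dim = as.integer(latent_dim),
              positive_rate = as.numeric(positive_rate),
              view_informativeness = view_informativeness,
              view_density = view_density,
              missing_gene_fraction = missing_gene_fraction,
              ess_sl_correlation = as.numeric(ess_sl_correlation),
              gi_noise_sd = as.numeric(gi_noise_sd),
              ess_noise_sd = as.numeric(ess_noise_sd),
              mutation_rate = as.numeric(mutation_rate),
              propensity_steepness = as.numeric(propensity_steepness),
              seed = as.integer(seed))
  if (!(cfg$positive_rate > 0 && cfg$positive_rate < 0.5)) {
    abort("positive_rate must lie in (0, 0.5)")
  }
  if (any(cfg$view_informativeness < 0 | cfg$view_informativeness > 1)) {
    abort("view informativeness values must lie in [0, 1]")
  }
  if (cfg$n_genes < 10) abort("n_genes must be at least 10")
  if (cfg$n_samples < 3) abort("n_samples must be at least 3")
  structure(cfg, class = "sl_synth_config")
}

#' Generate an Erdos-Renyi random view
#'
#' The random-network baseline: every unordered pair is an edge
#' independently with probability `density`; no self-edges.
#'
#' @param n_genes Number of genes, or a character vector of identifiers.
#' @param density Edge probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble `gene_a`, `gene_b`.
#' @export
generate_random_view <- function(n_genes, density, seed = 1L) {
  genes <- if (is.character(n_genes)) n_genes else synth_gene_names(n_genes)
  if (!(density >= 0 && density < 1)) abort("density must lie in [0, 1)")
  set.seed(seed)
  g <- igraph::sample_gnp(length(genes), density)
  el <- igraph::as_edgelist(g, names = FALSE)
  canonicalize_pairs(genes[el[, 1]], genes[el[, 2]])
}

synth_gene_names <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a full synthetic dataset
#'
#' See [synth_config()] for the generative model. GI scores are continuous
#' and calibrated so that the downstream labelling rule (score < -3)
#' recovers `positive_rate`; labels are never emitted directly, so the real
#' labelling path is exercised.
#'
#' @param cfg An [synth_config()].
#' @return List of class `"sl_dataset"`: `genes`, `gi` (score tibble),
#'   `edges` (named list of five edge tibbles), `profiles` (`expression`,
#'   `essentiality` matrices), `node_features` (raw tibble), `latent`
#'   (ground-truth factor matrix), `config`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  n <- cfg$n_genes
  genes <- synth_gene_names(n)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_pairs <- nrow(idx)

  set.seed(substream(cfg$seed, "latent"))
  U <- matrix(stats::rnorm(n * cfg$latent_dim), n, cfg$latent_dim)
  sim <- tcrossprod(U)[upper.tri(matrix(0, n, n))]
  zsim <- as.numeric(scale(sim))

  set.seed(substream(cfg$seed, "gi"))
  raw <- zsim + cfg$gi_noise_sd * stats::rnorm(n_pairs)
  q <- stats::quantile(raw, 1 - cfg$positive_rate, names = FALSE)
  gi_score <- -3 - 2 * (raw - q)
  realized <- mean(gi_score < -3)
  if (abs(realized - cfg$positive_rate) > 0.2 * cfg$positive_rate) {
    abort(sprintf("GI calibration failed: realized positive rate %.4f vs target %.4f",
                  realized, cfg$positive_rate))
  }
  gi <- tibble::tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                       gi_score = gi_score)

  # Informative views: logistic edge probability in the planted propensity,
  # centered at the propensity quantile matching the positive rate so that
  # high-propensity (SL-prone) pairs receive most of the informative mass;
  # the mixture preserves the view's expected density and degenerates to
  # pure Erdos-Renyi at informativeness 0.
  z_center <- stats::quantile(zsim, 1 - cfg$positive_rate, names = FALSE)
  lg <- stats::plogis(cfg$propensity_steepness * (zsim - z_center))
  edges <- list(SL = gi[gi$gi_score < -3, c("gene_a", "gene_b")])
  for (vid in c("PPI_PHYS", "PPI_GEN", "COEXPR", "COESS")) {
    set.seed(substream(cfg$seed, paste0("view-", vid)))
    w <- cfg$view_informativeness[[vid]]
    d <- cfg$view_density[[vid]]
    p_edge <- pmin((1 - w) * d + w * d * lg / mean(lg), 1)
    keep <- stats::rbinom(n_pairs, 1, p_edge) == 1
    edges[[vid]] <- gi[keep, c("gene_a", "gene_b")]
  }
  for (vid in names(edges)) {
    frac <- cfg$missing_gene_fraction[[vid]] %||% 0
    if (frac > 0) {
      set.seed(substream(cfg$seed, paste0("missing-", vid)))
      dropped <- sample(genes, floor(frac * n))
      e <- edges[[vid]]
      edges[[vid]] <- e[!(e$gene_a %in% dropped | e$gene_b %in% dropped), ]
    }
  }

  # SL-partner count under the labelling rule, for the essentiality plant
  sl_deg <- table(factor(c(edges$SL$gene_a, edges$SL$gene_b), levels = genes))
  sl_deg <- as.numeric(sl_deg)
  zdeg <- if (stats::sd(sl_deg) > 0) as.numeric(scale(sl_deg)) else rep(0, n)

  set.seed(substream(cfg$seed, "profiles"))
  rho <- cfg$ess_sl_correlation
  ess_gene <- rho * zdeg + sqrt(1 - rho^2) * stats::rnorm(n)
  samples <- sprintf("s%03d", seq_len(cfg$n_samples))
  expr_prof <- matrix(stats::rnorm(n * cfg$n_samples), n,
                      dimnames = list(genes, samples))
  ess_prof <- ess_gene + matrix(cfg$ess_noise_sd * stats::rnorm(n * cfg$n_samples),
                                n, dimnames = list(genes, samples))

  set.seed(substream(cfg$seed, "features"))
  node_features <- tibble::tibble(
    gene = genes,
    expression = stats::rnorm(n),
    copy_number = stats::rnorm(n),
    mutation = stats::rbinom(n, 1, cfg$mutation_rate),
    essentiality = ess_gene
  )

  structure(list(genes = genes, gi = gi, edges = edges,
                 profiles = list(expression = expr_prof, essentiality = ess_prof),
                 node_features = node_features, latent = U, config = cfg),
            class = "sl_dataset")
}

#' @export
print.sl_dataset <- function(x, ...) {
  cat(sprintf("<sl_dataset: %d genes, %d screened pairs (%.2f%% SL), views: %s>\n",
              length(x$genes), nrow(x$gi), 100 * mean(x$gi$gi_score < -3),
              paste(sprintf("%s=%d", names(x$edges),
                            vapply(x$edges, nrow, integer(1))), collapse = " ")))
  invisible(x)
}

#' Permute GI scores across pairs (label-shuffle null)
#'
#' Destroys the association between pairs and their lethality while
#' preserving the score distribution; a model trained on the shuffled
#' dataset should rank test pairs no better than chance.
#'
#' @param dataset An `"sl_dataset"`.
#' @param seed Integer seed.
#' @return The dataset with `gi$gi_score` permuted.
#' @export
shuffle_gi_scores <- function(dataset, seed = 1L) {
  set.seed(substream(seed, "shuffle-gi"))
  dataset$gi$gi_score <- sample(dataset$gi$gi_score)
  dataset
}

write_profile_matrix <- function(m, path) {
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a dataset bundle to a directory
#'
#' Emits the on-disk contracts of the readers: `gi_scores.tsv`, five
#' `edges_<VIEW>.tsv`, two profile matrices, `node_features.tsv` and a
#' `truth.json` with the latent factors and config. Byte-identical for
#' identical seeds.
#'
#' @param dataset An `"sl_dataset"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gi <- dataset$gi
  writeLines(paste(gi$gene_a, gi$gene_b,
                   format(gi$gi_score, digits = 15, trim = TRUE,
                          scientific = FALSE), sep = "\t"),
             file.path(dir, "gi_scores.tsv"))
  for (vid in names(dataset$edges)) {
    write_edge_list(dataset$edges[[vid]],
                    file.path(dir, sprintf("edges_%s.tsv", vid)))
  }
  write_profile_matrix(dataset$profiles$expression,
                       file.path(dir, "expression_profiles.tsv"))
  write_profile_matrix(dataset$profiles$essentiality,
                       file.path(dir, "essentiality_profiles.tsv"))
  nf <- dataset$node_features
  writeLines(c(paste(names(nf), collapse = "\t"),
               vapply(seq_len(nrow(nf)), function(i) {
                 paste(c(nf$gene[i],
                         format(c(nf$expression[i], nf$copy_number[i],
                                  nf$mutation[i], nf$essentiality[i]),
                                digits = 15, trim = TRUE, scientific = FALSE)),
                       collapse = "\t")
               }, character(1))),
             file.path(dir, "node_features.tsv"))
  jsonlite::write_json(list(config = unclass(dataset$config),
                            latent = dataset$latent),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
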