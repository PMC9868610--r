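# Shared fixtures: all built in code at test time.

sl_log_level("quiet")

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny symmetric adjacency from an edge index list
adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  A
}

# small model state with every weight and bias set to zero
zero_state <- function(n_features = 4, gcn_dims = c(6L, 4L),
                       head_dims = c(5L, 4L, 3L)) {
  st <- init_model(n_features, gcn_dims, head_dims, seed = 1)
  st$W0[] <- 0; st$W1[] <- 0
  st$head <- lapply(st$head, function(l) { l$W[] <- 0; l$b[] <- 0; l })
  st
}

# the fast training recipe used by test fits (small data, larger steps)
test_recipe <- function(seed, ...) {
  args <- utils::modifyList(list(seed = seed, learning_rate = 0.01,
                                 max_epochs = 600L, patience = 60L),
                            list(...))
  do.call(sl_config, args)
}

# small planted dataset for quick end-to-end fits
small_dataset <- function(seed = 1, n_genes = 120L) {
  generate_dataset(synth_config(n_genes = n_genes, seed = seed))
}
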