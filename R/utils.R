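# Internal helpers shared across modules: seed sub-streams, pair
# canonicalization, and lightweight structured logging to stderr.

# Derive a deterministic sub-seed (< 2^31) from a master seed and a stream
# name, so negative sampling, weight init and splitting draw from named
# independent streams while remaining reproducible from one integer.
substream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(seed) * 7919 + h * 31 + 1) %% 2147483647)
}

# Canonicalize unordered gene pairs as (min, max) by lexicographic order.
canonicalize_pairs <- function(gene_a, gene_b) {
  swap <- gene_a > gene_b
  first <- ifelse(swap, gene_b, gene_a)
  second <- ifelse(swap, gene_a, gene_b)
  tibble::tibble(gene_a = first, gene_b = second)
}

pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\r")

#' Set or query the logging level
#'
#' Messages emitted by `slview` readers, builders and the trainer go to
#' stderr through a single gate. Levels are `"debug"`, `"info"`, `"warn"`,
#' `"quiet"`.
#'
#' @param level New level; omit to query the current one.
#' @return The active level, invisibly when setting.
#' @export
sl_log_level <- function(level = NULL) {
  if (is.null(level)) {
    return(getOption("slview.log_level", "info"))
  }
  level <- match.arg(level, c("debug", "info", "warn", "quiet"))
  options(slview.log_level = level)
  invisible(level)
}

log_rank <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

sl_log <- function(msg, level = "info") {
  if (log_rank[[level]] >= log_rank[[sl_log_level()]]) {
    inform(sprintf("[slview %s] %s", toupper(level), msg))
  }
  invisible(NULL)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
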