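#' Permutation-test configuration
#'
#' The empirical null re-runs the propagation from randomly resampled seed
#' sets of the same size as the true seed set; a gene favored merely by the
#' network's structure scores highly under many random seed sets and is
#' discarded.
#'
#' @param n_sets number of random seed sets; default 1000.
#' @param set_size size of each random set; defaults to the observed seed
#'   set size at run time.
#' @param alpha significance cutoff; genes with `p < alpha` (strictly) are
#'   candidates; default 0.05.
#' @param rng_seed integer seed making the null sets reproducible.
#' @param exclude_seeds if `TRUE`, random sets are drawn from non-seed
#'   nodes only; by default they are drawn from all network nodes.
#' @return object of class `permutation_config`.
#' @export
permutation_config <- function(n_sets = 1000L, set_size = NULL,
                               alpha = 0.05, rng_seed = NULL,
                               exclude_seeds = FALSE) {
  stopifnot(n_sets >= 1, alpha >= 0, alpha <= 1)
  structure(list(n_sets = as.integer(n_sets), set_size = set_size,
                 alpha = alpha, rng_seed = rng_seed,
                 exclude_seeds = exclude_seeds),
            class = "permutation_config")
}

#' Sample random null seed sets
#'
#' Draws `n_sets` independent uniform samples without replacement of
#' `set_size` nodes from the network's node universe. Fully reproducible
#' from `rng_seed`.
#'
#' @param network a [weighted_network()] (or a character vector of nodes).
#' @param n_sets number of sets.
#' @param set_size nodes per set; must not exceed the universe size.
#' @param rng_seed integer seed.
#' @param exclude optional node identifiers removed from the universe
#'   before sampling (e.g. the true seeds).
#' @return list of `n_sets` character vectors.
#' @export
sample_null_seed_sets <- function(network, n_sets, set_size,
                                  rng_seed = NULL, exclude = NULL) {
  nodes <- if (inherits(network, "weighted_network")) network$nodes
           else as.character(network)
  if (!is.null(exclude)) nodes <- setdiff(nodes, exclude)
  if (set_size > length(nodes))
    stop("set_size (", set_size, ") exceeds the node universe (",
         length(nodes), ")")
  with_seed(rng_seed,
            replicate(n_sets, sample(nodes, set_size), simplify = FALSE))
}

#' Null propagation probabilities over random seed sets
#'
#' Runs one RWR per null seed set with the identical configuration used for
#' the observed run (the test is only valid under identical propagation)
#' and collects, for each gene of interest, its null probabilities.
#' Propagation is blocked so that many restart vectors iterate as columns
#' of one matrix product.
#'
#' @param M transition matrix from [transition_matrix()].
#' @param null_sets list of node-identifier vectors from
#'   [sample_null_seed_sets()].
#' @param config the [rwr_config()] of the observed run.
#' @param genes genes of interest (rows of the result); default all nodes.
#' @param block_size null sets propagated per matrix block.
#' @return numeric matrix, `length(genes)` rows by `length(null_sets)`
#'   columns. RWR non-convergence is propagated naming the offending set
#'   index.
#' @export
null_probabilities <- function(M, null_sets, config = rwr_config(),
                               genes = NULL, block_size = 200L) {
  nodes <- rownames(M)
  genes <- genes %||% nodes
  stopifnot(all(genes %in% nodes))
  n_sets <- length(null_sets)
  if (!n_sets) stop("no null sets given")
  out <- matrix(NA_real_, length(genes), n_sets,
                dimnames = list(genes, NULL))
  for (start in seq(1L, n_sets, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n_sets)
    P0 <- vapply(null_sets[idx], seed_vector, numeric(length(nodes)),
                 nodes = nodes)
    res <- tryCatch(rwr_iterate(M, P0, config), error = function(e) {
      stop("null propagation failed for set block starting at index ",
           idx[1], ": ", conditionMessage(e))
    })
    out[, idx] <- res$P[match(genes, nodes), , drop = FALSE]
  }
  out
}

#' Empirical permutation p-values
#'
#' For each gene, counts the null seed sets under which the gene's
#' propagation probability strictly exceeds its observed probability
#' (`theta`) and reports `p = theta / n_sets`. A null probability exactly
#' equal to the observed one does not count as an exceedance. Genes with
#' `p < alpha` (strictly) are flagged as candidates. A p-value of zero is
#' displayed as `"<1/n_sets"` since the test's resolution is `1/n_sets`.
#'
#' @param observed named probability vector from the observed [run_rwr()].
#' @param nulls matrix from [null_probabilities()] (genes x sets).
#' @param genes genes to score; must be rows of `nulls` and names of
#'   `observed`.
#' @param alpha candidate cutoff.
#' @return object of class `permutation_result`: data.frame with columns
#'   `gene`, `probability`, `theta`, `p_value`, `p_display`,
#'   `is_candidate`, plus attribute `n_sets`.
#' @export
empirical_pvalues <- function(observed, nulls, genes = rownames(nulls),
                              alpha = 0.05) {
  if (!all(genes %in% rownames(nulls)))
    stop("null probabilities missing for some genes")
  if (!all(genes %in% names(observed)))
    stop("observed probabilities missing for some genes")
  n_sets <- ncol(nulls)
  obs <- observed[genes]
  theta <- rowSums(nulls[genes, , drop = FALSE] > obs)
  p <- theta / n_sets
  res <- data.frame(
    gene = genes,
    probability = unname(obs),
    theta = as.integer(unname(theta)),
    p_value = unname(p),
    p_display = ifelse(theta == 0, sprintf("<%g", 1 / n_sets),
                       format(unname(p), trim = TRUE)),
    is_candidate = unname(p < alpha),
    stringsAsFactors = FALSE)
  structure(res, class = c("permutation_result", "data.frame"),
            n_sets = n_sets, alpha = alpha)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test over", attr(x, "n_sets"), "random seed sets\n")
  cat("  genes tested:", nrow(x), "\n")
  cat("  candidates (p <", attr(x, "alpha"), "):", sum(x$is_candidate), "\n")
  NextMethod()
}
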