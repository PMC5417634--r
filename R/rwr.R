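#' Random-walk-with-restart configuration
#'
#' Bundles the propagation constants: the restart probability `c` (the
#' fraction of probability mass re-injected at the seed nodes every
#' iteration), the L1 convergence tolerance, the probability cutoff used to
#' select high-scoring genes, an iteration cap, and the update rule.
#'
#' Under `update_rule = "standard"` (the default) the iteration is the
#' mass-conserving RWR form
#' \deqn{P_{i+1} = (1-c)\, M P_i + c P_0,}
#' where `M` is the column-stochastic transition matrix; its fixed point is
#' a probability distribution. `update_rule = "literal"` instead iterates
#' \eqn{P_{i+1} = M^T P_i + c P_0} with an un-damped matrix product; this
#' variant does not conserve probability mass and diverges for typical `c`,
#' and is retained only for comparison (see the vignette).
#'
#' @param restart_prob restart probability `c` in `(0, 1]`; default 0.8.
#' @param tolerance L1 convergence tolerance; default `1e-6`.
#' @param threshold probability cutoff for [select_rwr_genes()]; genes must
#'   exceed it strictly; default `1e-5`.
#' @param max_iter iteration cap; exceeding it is a non-convergence error.
#' @param update_rule `"standard"` or `"literal"`.
#' @return object of class `rwr_config`.
#' @export
rwr_config <- function(restart_prob = 0.8, tolerance = 1e-6,
                       threshold = 1e-5, max_iter = 10000L,
                       update_rule = c("standard", "literal")) {
  update_rule <- match.arg(update_rule)
  stopifnot(restart_prob > 0, restart_prob <= 1,
            tolerance > 0, threshold >= 0, max_iter >= 1)
  structure(list(restart_prob = restart_prob, tolerance = tolerance,
                 threshold = threshold, max_iter = as.integer(max_iter),
                 update_rule = update_rule),
            class = "rwr_config")
}

#' Column-stochastic transition matrix of a weighted network
#'
#' Builds the symmetric weighted adjacency (edge scores as weights) and
#' normalizes each column to sum to one, so that a walker at node `j` moves
#' to neighbor `i` with probability proportional to the edge score. An
#' isolated node receives a unit self-loop, which keeps the matrix
#' column-stochastic (isolated nodes can never gain mass beyond restart
#' anyway).
#'
#' @param network a [weighted_network()].
#' @return a sparse `dgCMatrix` with node identifiers as dimnames; every
#'   column sums to 1 within `1e-12`.
#' @export
transition_matrix <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (!n) stop("empty network")
  e <- network$edges
  i <- match(e$from, nodes); j <- match(e$to, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = as.numeric(c(e$score, e$score)),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(A)
  isolated <- deg == 0
  if (any(isolated)) {
    idx <- which(isolated)
    A <- A + Matrix::sparseMatrix(i = idx, j = idx, x = 1,
                                  dims = c(n, n),
                                  dimnames = list(nodes, nodes))
    deg[isolated] <- 1
  }
  M <- A %*% Matrix::Diagonal(n, 1 / deg)
  dimnames(M) <- list(nodes, nodes)
  methods::as(M, "CsparseMatrix")
}

#' Initial probability vector over seed nodes
#'
#' Each seed receives mass `1/n_seeds`; all other nodes receive zero. When
#' a seed gene maps to several protein isoform nodes, pass the mapping from
#' [map_seeds_to_network()]: the gene's `1/n_genes` share is then split
#' equally among its nodes.
#'
#' @param seeds a [seed_set()]/character vector of node identifiers, or a
#'   named list (gene -> node identifiers) as returned in
#'   `map_seeds_to_network()$mapping`.
#' @param nodes character vector giving the node ordering of the transition
#'   matrix.
#' @return named numeric vector summing to 1.
#' @export
seed_vector <- function(seeds, nodes) {
  p0 <- setNames(numeric(length(nodes)), nodes)
  if (is.list(seeds)) {
    if (!length(seeds)) stop("empty seed set")
    share <- 1 / length(seeds)
    for (node_ids in seeds) {
      if (!all(node_ids %in% nodes))
        stop("seed node(s) not in network: ",
             paste(setdiff(node_ids, nodes), collapse = ", "))
      p0[node_ids] <- p0[node_ids] + share / length(node_ids)
    }
  } else {
    seeds <- as.character(seeds)
    if (!length(seeds)) stop("empty seed set")
    if (!all(seeds %in% nodes))
      stop("seed node(s) not in network: ",
           paste(setdiff(seeds, nodes), collapse = ", "))
    p0[seeds] <- 1 / length(seeds)
  }
  p0
}

# Shared iteration engine: propagates one or more initial vectors (columns
# of P0) simultaneously until every column's L1 update gap is below tol.
rwr_iterate <- function(M, P0, config) {
  c0 <- config$restart_prob
  P <- P0
  standard <- config$update_rule == "standard"
  Mt <- if (!standard) Matrix::t(M)
  for (it in seq_len(config$max_iter)) {
    P_new <- if (standard) {
      (1 - c0) * (M %*% P) + c0 * P0
    } else {
      Mt %*% P + c0 * P0
    }
    P_new <- as.matrix(P_new)
    gap <- max(colSums(abs(P_new - P)))
    P <- P_new
    if (gap < config$tolerance)
      return(list(P = P, iterations = it, converged = TRUE, gap = gap))
  }
  cond <- structure(
    class = c("fruitwalk_nonconvergence", "error", "condition"),
    list(message = sprintf(
           "RWR did not converge within %d iterations (last L1 gap %.3g)",
           config$max_iter, gap),
         call = sys.call(-1), gap = gap, iterations = config$max_iter,
         last_norm = max(colSums(abs(P)))))
  stop(cond)
}

#' Run random walk with restart
#'
#' Iterates the propagation update from the seed-restart vector `p0` until
#' the L1 difference between successive vectors falls below the tolerance.
#' Under the default update rule the result is the stationary distribution
#' of a walker that follows network edges with probability `1 - c` and
#' restarts at the seeds with probability `c`; entries are the propagation
#' probabilities used to rank genes by proximity to the seed set.
#'
#' @param M transition matrix from [transition_matrix()].
#' @param p0 initial vector from [seed_vector()]; must sum to 1.
#' @param config an [rwr_config()].
#' @return named numeric vector of probabilities with attributes
#'   `iterations` and `converged`. Non-convergence within `max_iter` raises
#'   an error of class `fruitwalk_nonconvergence` carrying the last L1 gap.
#' @examples
#' net <- weighted_network("a", "b", 900L)
#' M <- transition_matrix(net)
#' p <- run_rwr(M, seed_vector("a", rownames(M)))
#' p  # seed retains 5/6 of the mass at c = 0.8
#' @export
run_rwr <- function(M, p0, config = rwr_config()) {
  stopifnot(inherits(config, "rwr_config"))
  if (length(p0) != nrow(M)) stop("p0 length does not match matrix")
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  res <- rwr_iterate(M, matrix(p0, ncol = 1), config)
  structure(setNames(res$P[, 1], rownames(M)),
            iterations = res$iterations, converged = res$converged)
}

#' Direct linear solve of the RWR stationary distribution
#'
#' Solves \eqn{p = (1-c) M p + c p_0} exactly by a dense linear solve. This
#' is an independent oracle for checking the iterative propagation on small
#' graphs; it is guarded to at most 2000 nodes.
#'
#' @param M transition matrix.
#' @param p0 initial vector.
#' @param restart_prob restart probability `c`.
#' @return named numeric vector, the exact stationary distribution.
#' @export
solve_rwr_direct <- function(M, p0, restart_prob = 0.8) {
  n <- nrow(M)
  if (n > 2000) stop("direct solve guarded to <= 2000 nodes")
  stopifnot(restart_prob > 0, restart_prob <= 1, length(p0) == n)
  A <- diag(n) - (1 - restart_prob) * as.matrix(M)
  setNames(as.numeric(solve(A, restart_prob * p0)), rownames(M))
}

#' Select high-probability non-seed genes
#'
#' Returns the non-seed genes whose propagation probability strictly
#' exceeds the configured threshold, sorted by descending probability with
#' lexicographic tie-breaking.
#'
#' @param p probability vector from [run_rwr()].
#' @param seeds seed node identifiers (excluded from the result).
#' @param config an [rwr_config()]; only `threshold` is used.
#' @return data.frame with columns `gene` and `probability`.
#' @export
select_rwr_genes <- function(p, seeds, config = rwr_config()) {
  seeds <- if (is.list(seeds)) unlist(seeds, use.names = FALSE)
           else as.character(seeds)
  keep <- !(names(p) %in% seeds) & p > config$threshold
  genes <- names(p)[keep]
  prob <- unname(p[keep])
  o <- order(-prob, genes)
  data.frame(gene = genes[o], probability = prob[o],
             stringsAsFactors = FALSE)
}
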