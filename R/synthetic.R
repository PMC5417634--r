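#' Specification of a planted-module benchmark
#'
#' Describes a synthetic stand-in for the real inputs: a sparse weighted
#' interaction network with integer scores in `[150, 999]` containing one
#' densely connected, strongly scored, co-annotated "fruit module"; part of
#' the module is used as the validated seed set and the rest is held out as
#' positives to recover. Defaults are the strong-signal study conditions
#' used throughout the package's benchmarks.
#'
#' @param n_nodes total number of genes.
#' @param module_size number of planted module genes.
#' @param p_in,p_out Bernoulli edge probabilities within the module /
#'   elsewhere.
#' @param score_in,score_out integer score ranges (length-2, within
#'   `[150, 999]`) for module / background edges.
#' @param seed_fraction fraction of module genes used as seeds (the rest
#'   are held-out positives).
#' @param n_terms annotation universe size.
#' @param n_module_terms number of terms forming the module block.
#' @param share_in,share_out probability that a module / background gene
#'   carries each module term.
#' @param background_rate probability that any gene carries each
#'   non-module term.
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return object of class `planted_module_spec`.
#' @export
planted_module_spec <- function(n_nodes = 300L, module_size = 30L,
                                p_in = 0.6, p_out = 0.01,
                                score_in = c(900L, 999L),
                                score_out = c(150L, 400L),
                                seed_fraction = 0.5,
                                n_terms = 60L, n_module_terms = 10L,
                                share_in = 0.9, share_out = 0.02,
                                background_rate = 0.05,
                                rng_seed = 1L) {
  stopifnot(module_size <= n_nodes, module_size >= 2,
            p_out >= 0, p_in >= p_out, p_in <= 1,
            length(score_in) == 2L, length(score_out) == 2L,
            all(c(score_in, score_out) >= 150L),
            all(c(score_in, score_out) <= 999L),
            score_in[1] <= score_in[2], score_out[1] <= score_out[2],
            seed_fraction > 0, seed_fraction < 1,
            n_module_terms <= n_terms,
            share_in >= 0, share_in <= 1, share_out >= 0, share_out <= 1,
            background_rate >= 0, background_rate <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 module_size = as.integer(module_size),
                 p_in = p_in, p_out = p_out,
                 score_in = as.integer(score_in),
                 score_out = as.integer(score_out),
                 seed_fraction = seed_fraction,
                 n_terms = as.integer(n_terms),
                 n_module_terms = as.integer(n_module_terms),
                 share_in = share_in, share_out = share_out,
                 background_rate = background_rate,
                 rng_seed = rng_seed),
            class = "planted_module_spec")
}

#' Generate a planted-module network
#'
#' Planted-partition topology: every unordered gene pair gets an edge with
#' probability `p_in` when both genes are module members and `p_out`
#' otherwise; edge scores are drawn uniformly from `score_in` inside the
#' module and `score_out` elsewhere. Reproducible from the spec's
#' `rng_seed` (edge and score draws use named substreams).
#'
#' @param spec a [planted_module_spec()].
#' @return list with `network` (a [weighted_network()]; isolated genes are
#'   kept as nodes) and `module` (character vector of module gene ids).
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_module_spec"))
  n <- spec$n_nodes
  nodes <- sprintf("g%04d", seq_len(n))
  module <- nodes[seq_len(spec$module_size)]
  pairs <- utils::combn(n, 2L)
  in_module <- pairs[1, ] <= spec$module_size & pairs[2, ] <= spec$module_size
  p_edge <- ifelse(in_module, spec$p_in, spec$p_out)
  present <- with_seed(derive_seed(spec$rng_seed, "edges"),
                       runif(ncol(pairs)) < p_edge)
  i <- pairs[1, present]; j <- pairs[2, present]
  em <- in_module[present]
  score <- with_seed(derive_seed(spec$rng_seed, "scores"), {
    lo <- ifelse(em, spec$score_in[1], spec$score_out[1])
    hi <- ifelse(em, spec$score_in[2], spec$score_out[2])
    lo + floor(runif(length(lo)) * (hi - lo + 1))
  })
  net <- weighted_network(nodes[i], nodes[j], as.integer(score),
                          nodes = nodes)
  list(network = net, module = module)
}

#' Generate a synthetic annotation catalog
#'
#' A block of "module terms" is carried by module genes with probability
#' `share_in` and by background genes with probability `share_out`; the
#' remaining terms are assigned to every gene uniformly at
#' `background_rate`. Genes may end up unannotated (and are flagged by the
#' catalog), as in real annotation tables.
#'
#' @param spec a [planted_module_spec()].
#' @param module module gene ids from [generate_planted_network()].
#' @return an [annotation_catalog()] over all `n_nodes` genes.
#' @export
generate_annotations <- function(spec, module) {
  stopifnot(inherits(spec, "planted_module_spec"))
  n <- spec$n_nodes
  nodes <- sprintf("g%04d", seq_len(n))
  stopifnot(all(module %in% nodes))
  mod_terms <- sprintf("MT:%03d", seq_len(spec$n_module_terms))
  bg_terms <- if (spec$n_terms > spec$n_module_terms)
    sprintf("BT:%03d", seq_len(spec$n_terms - spec$n_module_terms))
  else character()
  with_seed(derive_seed(spec$rng_seed, "annotations"), {
    sets <- lapply(nodes, function(g) {
      p_mod <- if (g %in% module) spec$share_in else spec$share_out
      terms <- mod_terms[runif(length(mod_terms)) < p_mod]
      c(terms, bg_terms[runif(length(bg_terms)) < spec$background_rate])
    })
    names(sets) <- nodes
    annotation_catalog(sets)
  })
}

#' Split the planted module into seeds and held-out positives
#'
#' Uniform random split: `floor(seed_fraction * module_size)` genes become
#' the seed set (at least one gene is always held out). Reproducible from
#' `rng_seed`.
#'
#' @param module module gene ids.
#' @param seed_fraction fraction used as seeds.
#' @param rng_seed integer seed.
#' @return list with `seeds` (a [seed_set()]) and `held_out` (character).
#' @export
split_seeds <- function(module, seed_fraction, rng_seed = NULL) {
  m <- length(module)
  n_seed <- floor(seed_fraction * m)
  if (n_seed < 1L || n_seed >= m)
    stop("seed_fraction ", seed_fraction, " leaves an empty part for ",
         m, " module genes")
  pick <- with_seed(derive_seed(rng_seed, "split"), sample(m, n_seed))
  list(seeds = seed_set(sort(module[pick]), provenance = "planted module"),
       held_out = sort(module[-pick]))
}

#' Score recovery of held-out module genes
#'
#' Precision and recall of the held-out positives among the putative genes
#' (precision is 0 when the putative set is empty), plus the positives'
#' ranks in the propagation ordering when supplied.
#'
#' @param putative character vector of putative gene ids.
#' @param held_out character vector of held-out positives (non-empty).
#' @param survivor_counts optional named numeric vector of per-stage
#'   survivor counts (echoed in the report).
#' @param ranking optional character vector of non-seed genes in
#'   descending propagation order, used to report positives' ranks.
#' @return object of class `recovery_report`: list with `precision`,
#'   `recall`, `f1`, `n_putative`, `n_held_out`, `ranks`,
#'   `survivor_counts`.
#' @export
evaluate_recovery <- function(putative, held_out, survivor_counts = NULL,
                              ranking = NULL) {
  if (!length(held_out)) stop("held-out positive set is empty")
  putative <- unique(as.character(putative))
  held_out <- unique(as.character(held_out))
  tp <- length(intersect(putative, held_out))
  precision <- if (length(putative)) tp / length(putative) else 0
  recall <- tp / length(held_out)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  ranks <- if (!is.null(ranking)) {
    r <- match(held_out, ranking)
    setNames(r, held_out)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 n_putative = length(putative),
                 n_held_out = length(held_out),
                 ranks = ranks, survivor_counts = survivor_counts),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Recovery of %d held-out positives among %d putative genes:\n",
    x$n_held_out, x$n_putative))
  cat(sprintf("  precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  if (!is.null(x$survivor_counts)) {
    cat("  funnel:", paste(names(x$survivor_counts),
                           x$survivor_counts, sep = "=", collapse = " -> "),
        "\n")
  }
  invisible(x)
}
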