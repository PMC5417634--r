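#' Maximum interaction score against the seed set
#'
#' For each gene, the strongest direct interaction with any seed node:
#' `MIS(g) = max { S_I(g, s) : s in seeds }` over the network's edge
#' scores. A gene with no direct seed neighbor gets `NA`. 900 is the
#' STRING "highest confidence" floor used as the downstream threshold.
#'
#' @param genes character vector of node identifiers.
#' @param seeds seed node identifiers.
#' @param network a [weighted_network()].
#' @return named integer vector (NA where no seed edge exists).
#' @export
max_interaction_score <- function(genes, seeds, network) {
  stopifnot(inherits(network, "weighted_network"))
  genes <- as.character(genes)
  seeds <- if (is.list(seeds)) unlist(seeds, use.names = FALSE)
           else as.character(seeds)
  missing <- setdiff(genes, network$nodes)
  if (length(missing))
    stop("gene(s) not in network: ", paste(head(missing, 5), collapse = ", "))
  e <- network$edges
  # edges touching a seed, keyed by the other endpoint
  fs <- e$from %in% seeds
  ts <- e$to %in% seeds
  other <- c(e$to[fs], e$from[ts])
  sc <- c(e$score[fs], e$score[ts])
  best <- tapply(sc, other, max)
  out <- setNames(rep(NA_integer_, length(genes)), genes)
  hit <- genes %in% names(best)
  out[hit] <- as.integer(best[genes[hit]])
  out
}

#' Build functional annotation vectors
#'
#' Represents each gene as a non-negative vector over the fixed, sorted
#' universe of annotation terms (GO terms and KEGG pathways), for cosine
#' comparison against the seeds.
#'
#' Two vectorizers are available. `"binary"` (default) sets component `t`
#' to 1 iff the gene is annotated to term `t`. `"enrichment"` sets
#' component `t` to \eqn{-\log_{10}} of the hypergeometric upper-tail
#' p-value of the overlap between the annotations of the gene's network
#' neighborhood (the gene plus its direct neighbors, restricted to
#' cataloged genes) and term `t`'s annotated gene set, with 0 when the
#' overlap is empty.
#'
#' @param catalog an [annotation_catalog()].
#' @param genes genes to vectorize (rows); genes absent from the catalog
#'   get an all-zero vector and are recorded in the `"zero_genes"`
#'   attribute.
#' @param vectorizer `"binary"` or `"enrichment"`.
#' @param universe term universe (columns); defaults to the sorted union of
#'   all catalog terms.
#' @param network required for `"enrichment"`: the [weighted_network()]
#'   supplying neighborhoods.
#' @return numeric matrix `length(genes)` x `length(universe)` with
#'   dimnames, attribute `"zero_genes"` listing all-zero rows and
#'   `"vectorizer"` recording the method.
#' @export
build_annotation_vectors <- function(catalog, genes,
                                     vectorizer = c("binary", "enrichment"),
                                     universe = NULL, network = NULL) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  vectorizer <- match.arg(vectorizer)
  genes <- as.character(genes)
  universe <- universe %||% sort(unique(unlist(catalog, use.names = FALSE)))
  V <- matrix(0, length(genes), length(universe),
              dimnames = list(genes, universe))
  if (vectorizer == "binary") {
    for (g in genes) {
      terms <- catalog[[g]]
      if (length(terms)) V[g, intersect(terms, universe)] <- 1
    }
  } else {
    if (is.null(network))
      stop("the enrichment vectorizer needs the interaction network")
    cataloged <- names(catalog)
    N <- length(cataloged)
    # genes annotated per term
    term_genes <- split(rep(cataloged, lengths(catalog)),
                        unlist(catalog, use.names = FALSE))
    K <- setNames(integer(length(universe)), universe)
    K[names(term_genes)] <- lengths(term_genes)
    e <- network$edges
    for (g in genes) {
      nb <- unique(c(g, e$to[e$from == g], e$from[e$to == g]))
      nb <- nb[nb %in% cataloged]
      if (!length(nb)) next
      counts <- table(unlist(catalog[nb], use.names = FALSE))
      hit <- intersect(names(counts), universe)
      if (!length(hit)) next
      k <- as.integer(counts[hit])
      pv <- phyper(k - 1L, K[hit], N - K[hit], length(nb),
                   lower.tail = FALSE)
      V[g, hit] <- -log10(pmax(pv, .Machine$double.xmin))
    }
  }
  zero <- genes[rowSums(V) == 0]
  structure(V, zero_genes = zero, vectorizer = vectorizer)
}

#' Cosine similarity of two annotation vectors
#'
#' `Gamma(g, g') = V(g) . V(g') / (||V(g)|| ||V(g')||)`, defined as 0 when
#' either vector is all-zero so that unannotated genes flow through the
#' pipeline and simply fail the functional filter.
#'
#' @param v,w numeric vectors over the same term universe.
#' @return similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(v, w) {
  if (length(v) != length(w))
    stop("annotation vectors have different lengths")
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) return(0)
  sum(v * w) / (nv * nw)
}

#' Maximum function score against the seed set
#'
#' For each gene, the highest cosine similarity between its annotation
#' vector and any seed's: `MFS(g) = max { Gamma(g, s) : s in seeds }`.
#' `NA` only when the gene's own vector is all-zero; seeds with all-zero
#' vectors contribute similarity 0.
#'
#' @param genes genes to score (must be rows of `vectors`).
#' @param seeds seed identifiers (rows of `vectors`).
#' @param vectors matrix from [build_annotation_vectors()] covering genes
#'   and seeds.
#' @return named numeric vector in `[0, 1]`, `NA` for zero-vector genes.
#' @export
max_function_score <- function(genes, seeds, vectors) {
  genes <- as.character(genes)
  seeds <- if (is.list(seeds)) unlist(seeds, use.names = FALSE)
           else as.character(seeds)
  stopifnot(all(genes %in% rownames(vectors)),
            all(seeds %in% rownames(vectors)))
  G <- vectors[genes, , drop = FALSE]
  S <- vectors[seeds, , drop = FALSE]
  gn <- sqrt(rowSums(G^2))
  sn <- sqrt(rowSums(S^2))
  keep_s <- sn > 0
  out <- setNames(rep(NA_real_, length(genes)), genes)
  nonzero_g <- gn > 0
  if (any(nonzero_g) && any(keep_s)) {
    sims <- (G[nonzero_g, , drop = FALSE] %*%
               t(S[keep_s, , drop = FALSE])) /
      outer(gn[nonzero_g], sn[keep_s])
    out[nonzero_g] <- apply(sims, 1, max)
  } else if (any(nonzero_g)) {
    out[nonzero_g] <- 0  # all seed vectors zero
  }
  out
}

#' Score candidate genes' linkage to the seed set
#'
#' Computes, for each candidate gene, the maximum interaction score (MIS)
#' over direct seed edges and the maximum function score (MFS) over
#' annotation-vector cosines, and applies the putative-gene thresholds:
#' MIS no less than `mis_threshold` (inclusive) and MFS strictly larger
#' than `mfs_threshold`.
#'
#' @param genes candidate gene identifiers (network nodes).
#' @param seeds seed node identifiers.
#' @param network a [weighted_network()].
#' @param catalog an [annotation_catalog()], or `NULL` to skip MFS (all
#'   `NA`, nothing passes the functional filter).
#' @param vectorizer passed to [build_annotation_vectors()].
#' @param mis_threshold inclusive MIS cutoff; default 900.
#' @param mfs_threshold exclusive MFS cutoff; default 0.9.
#' @param go_closure propagate annotations to ontology ancestors before
#'   vectorization (needs `ontology`).
#' @param ontology an [parse_obo()] result, used when `go_closure = TRUE`.
#' @return data.frame `gene`, `mis`, `mfs`, `pass_mis`, `pass_mfs`,
#'   `is_putative`.
#' @export
linkage_scores <- function(genes, seeds, network, catalog = NULL,
                           vectorizer = c("binary", "enrichment"),
                           mis_threshold = 900, mfs_threshold = 0.9,
                           go_closure = FALSE, ontology = NULL) {
  vectorizer <- match.arg(vectorizer)
  genes <- as.character(genes)
  seed_ids <- if (is.list(seeds)) unlist(seeds, use.names = FALSE)
              else as.character(seeds)
  mis <- max_interaction_score(genes, seed_ids, network)
  if (!is.null(catalog)) {
    if (go_closure) {
      if (is.null(ontology)) stop("go_closure = TRUE needs 'ontology'")
      catalog <- annotate_with_ancestors(catalog, ontology)
    }
    # vectors are built on normalized gene ids so that protein-level node
    # ids join the gene-level catalog
    gene_ids <- normalize_gene_ids(genes)
    seed_genes <- unique(normalize_gene_ids(seed_ids))
    all_ids <- unique(c(gene_ids, seed_genes))
    V <- build_annotation_vectors(catalog, all_ids, vectorizer,
                                  network = network)
    mfs <- unname(max_function_score(gene_ids, seed_genes, V))
  } else {
    mfs <- rep(NA_real_, length(genes))
  }
  pass_mis <- !is.na(mis) & mis >= mis_threshold
  pass_mfs <- !is.na(mfs) & mfs > mfs_threshold
  data.frame(gene = genes, mis = unname(mis), mfs = mfs,
             pass_mis = pass_mis, pass_mfs = pass_mfs,
             is_putative = pass_mis & pass_mfs,
             stringsAsFactors = FALSE)
}

#' Final putative-gene filter
#'
#' Keeps candidate records with `mis >= mis_threshold` (the boundary value
#' passes) and `mfs > mfs_threshold` (the boundary value fails), sorted by
#' descending propagation probability. Records with an absent score are
#' dropped.
#'
#' @param records data.frame with at least `gene`, `mis`, `mfs` and
#'   (optionally) `rwr_probability`/`probability` columns.
#' @param mis_threshold inclusive MIS cutoff; default 900.
#' @param mfs_threshold exclusive MFS cutoff; default 0.9.
#' @return the filtered, re-sorted data.frame.
#' @export
final_filter <- function(records, mis_threshold = 900, mfs_threshold = 0.9) {
  keep <- !is.na(records$mis) & records$mis >= mis_threshold &
          !is.na(records$mfs) & records$mfs > mfs_threshold
  out <- records[keep, , drop = FALSE]
  pcol <- intersect(c("rwr_probability", "probability"), names(out))
  if (length(pcol)) out <- out[order(-out[[pcol[1]]], out$gene), ,
                               drop = FALSE]
  rownames(out) <- NULL
  out
}
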