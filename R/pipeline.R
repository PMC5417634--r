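#' Prioritize candidate genes by network propagation
#'
#' The package's main entry point. Runs the four-stage pipeline on a
#' weighted interaction network seeded with validated genes:
#'
#' 1. **Propagation** — random walk with restart from the seed set; the
#'    non-seed genes whose stationary probability strictly exceeds
#'    `rwr$threshold` are the *RWR genes*.
#' 2. **Permutation screen** — the propagation is re-run from `n_sets`
#'    random seed sets of the same size; each RWR gene gets an empirical
#'    p-value (fraction of random sets giving it a strictly higher
#'    probability) and genes with `p < alpha` are the *candidate genes*.
#' 3. **Interaction linkage** — each candidate's maximum direct interaction
#'    score against any seed (MIS) must be at least `mis_threshold`.
#' 4. **Functional linkage** — each candidate's maximum annotation-vector
#'    cosine against any seed (MFS) must exceed `mfs_threshold`.
#'
#' Candidates passing both linkage filters are the *putative genes*.
#'
#' @param network a [weighted_network()].
#' @param seeds a [seed_set()] of gene identifiers; identifiers that are
#'   not network nodes are mapped via [map_seeds_to_network()].
#' @param catalog optional [annotation_catalog()] of GO/KEGG annotations
#'   used for the functional filter; without it MFS is `NA` and no gene is
#'   putative.
#' @param rwr an [rwr_config()].
#' @param perm a [permutation_config()]; its `rng_seed` (or the `seed`
#'   shortcut argument) makes the permutation null reproducible.
#' @param mis_threshold inclusive MIS cutoff; default 900.
#' @param mfs_threshold exclusive MFS cutoff; default 0.9.
#' @param vectorizer annotation vectorizer, see
#'   [build_annotation_vectors()].
#' @param go_closure,ontology optional ancestor closure of annotations, see
#'   [linkage_scores()].
#' @param seed convenience override for `perm$rng_seed`.
#' @return object of class `gene_prioritization`; see
#'   [print.gene_prioritization()], [summary.gene_prioritization()],
#'   [as.data.frame.gene_prioritization()]. Key components:
#'   `records` (one row per RWR gene: probability, theta, p-value, MIS,
#'   MFS, stage flags), `putative` (character vector), `probabilities`
#'   (full propagation vector), `manifest` (stage survivor counts and the
#'   configuration echo).
#' @examples
#' spec <- planted_module_spec(n_nodes = 120, module_size = 16, rng_seed = 7)
#' sim <- generate_planted_network(spec)
#' split <- split_seeds(sim$module, 0.5, rng_seed = 7)
#' catalog <- generate_annotations(spec, sim$module)
#' fit <- prioritize_genes(sim$network, split$seeds, catalog,
#'   perm = permutation_config(n_sets = 50, rng_seed = 7))
#' fit
#' @export
prioritize_genes <- function(network, seeds, catalog = NULL,
                             rwr = rwr_config(),
                             perm = permutation_config(),
                             mis_threshold = 900, mfs_threshold = 0.9,
                             vectorizer = c("binary", "enrichment"),
                             go_closure = FALSE, ontology = NULL,
                             seed = NULL) {
  stopifnot(inherits(network, "weighted_network"),
            inherits(rwr, "rwr_config"),
            inherits(perm, "permutation_config"))
  vectorizer <- match.arg(vectorizer)
  if (!is.null(seed)) perm$rng_seed <- seed

  seeds <- if (inherits(seeds, "seed_set")) seeds else seed_set(seeds)
  mapping <- NULL
  unmapped <- character()
  if (!all(seeds %in% network$nodes)) {
    mapped <- map_seeds_to_network(seeds, network)
    mapping <- mapped$mapping
    unmapped <- mapped$unmapped
    seed_nodes <- unclass(mapped$seeds)
  } else {
    seed_nodes <- unclass(seeds)
  }

  M <- transition_matrix(network)
  p0 <- seed_vector(mapping %||% seed_nodes, rownames(M))
  p <- run_rwr(M, p0, rwr)
  rwr_tab <- select_rwr_genes(p, seed_nodes, rwr)

  set_size <- perm$set_size %||% length(seed_nodes)
  null_sets <- sample_null_seed_sets(
    network, perm$n_sets, set_size, rng_seed = perm$rng_seed,
    exclude = if (perm$exclude_seeds) seed_nodes)
  nulls <- null_probabilities(M, null_sets, rwr, genes = rwr_tab$gene)
  ptab <- empirical_pvalues(p, nulls, rwr_tab$gene, alpha = perm$alpha)

  candidates <- ptab$gene[ptab$is_candidate]
  link <- linkage_scores(candidates, seed_nodes, network, catalog,
                         vectorizer = vectorizer,
                         mis_threshold = mis_threshold,
                         mfs_threshold = mfs_threshold,
                         go_closure = go_closure, ontology = ontology)

  records <- data.frame(
    gene = ptab$gene,
    probability = ptab$probability,
    theta = ptab$theta,
    p_value = ptab$p_value,
    p_display = ptab$p_display,
    is_candidate = ptab$is_candidate,
    mis = NA_integer_, mfs = NA_real_, is_putative = FALSE,
    stringsAsFactors = FALSE)
  ri <- match(link$gene, records$gene)
  records$mis[ri] <- link$mis
  records$mfs[ri] <- link$mfs
  records$is_putative[ri] <- link$is_putative
  putative <- records$gene[records$is_putative]

  manifest <- list(
    counts = c(nodes = length(network$nodes),
               edges = nrow(network$edges),
               seeds_mapped = length(seed_nodes),
               seeds_unmapped = length(unmapped),
               rwr_genes = nrow(rwr_tab),
               candidates = length(candidates),
               putative = length(putative)),
    config = list(rwr = unclass(rwr), perm = unclass(perm),
                  mis_threshold = mis_threshold,
                  mfs_threshold = mfs_threshold,
                  vectorizer = vectorizer, go_closure = go_closure),
    unmapped_seeds = unmapped,
    timestamp = format(Sys.time(), tz = "UTC"),
    version = as.character(utils::packageVersion("fruitwalk")))

  structure(list(records = records, putative = putative,
                 probabilities = p, seeds = seed_nodes,
                 seed_mapping = mapping, network = network,
                 manifest = manifest),
            class = "gene_prioritization")
}

#' @describeIn prioritize_genes stage-funnel summary.
#' @param x,object a `gene_prioritization` object.
#' @param ... unused.
#' @export
print.gene_prioritization <- function(x, ...) {
  ct <- x$manifest$counts
  cat("Gene prioritization by network propagation\n")
  cat(sprintf("  network: %d nodes, %d edges; %d seed nodes (%d unmapped)\n",
              ct["nodes"], ct["edges"], ct["seeds_mapped"],
              ct["seeds_unmapped"]))
  cat(sprintf("  funnel: %d RWR genes -> %d candidates -> %d putative\n",
              ct["rwr_genes"], ct["candidates"], ct["putative"]))
  invisible(x)
}

#' @describeIn prioritize_genes top putative genes with their evidence.
#' @param n rows to display.
#' @export
summary.gene_prioritization <- function(object, n = 10L, ...) {
  print(object)
  top <- final_filter(object$records,
                      object$manifest$config$mis_threshold,
                      object$manifest$config$mfs_threshold)
  if (nrow(top)) {
    cat("\nTop putative genes:\n")
    show <- head(top[, c("gene", "probability", "p_display", "mis", "mfs")],
                 n)
    names(show)[3] <- "p_value"
    print(show, row.names = FALSE, digits = 4)
  } else {
    cat("\nNo putative genes at the current thresholds.\n")
  }
  invisible(object)
}

#' @describeIn prioritize_genes one row per RWR gene (the evidence table).
#' @export
as.data.frame.gene_prioritization <- function(x, ...) {
  x$records
}

#' @describeIn prioritize_genes funnel barplot and probability profile.
#' @export
plot.gene_prioritization <- function(x, ...) {
  ct <- x$manifest$counts
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(ct[c("rwr_genes", "candidates", "putative")],
                    names.arg = c("RWR", "candidate", "putative"),
                    ylab = "genes", main = "Selection funnel",
                    col = "steelblue")
  pr <- sort(x$records$probability, decreasing = TRUE)
  graphics::plot(seq_along(pr), pr, log = "y", type = "l",
                 xlab = "rank", ylab = "propagation probability",
                 main = "RWR gene probabilities")
  thr <- x$manifest$config$rwr$threshold
  graphics::abline(h = thr, lty = 2, col = "grey40")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Persists every stage's table so that any stage can be inspected or
#' re-analyzed in isolation: the full probability vector, the permutation
#' table, the linkage table, the putative gene list and a key-value
#' manifest of survivor counts and configuration.
#'
#' @param fit a [prioritize_genes()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_prioritization <- function(fit, dir) {
  stopifnot(inherits(fit, "gene_prioritization"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  prob <- data.frame(gene = names(fit$probabilities),
                     probability = unname(fit$probabilities))
  prob <- prob[order(-prob$probability, prob$gene), ]
  tsv(prob, "probabilities.tsv")
  tsv(fit$records[, c("gene", "probability", "theta", "p_value",
                      "is_candidate")], "permutation.tsv")
  tsv(fit$records[, c("gene", "probability", "p_value", "mis", "mfs",
                      "is_putative")], "linkage.tsv")
  writeLines(fit$putative, file.path(dir, "putative_genes.txt"))
  ct <- fit$manifest$counts
  writeLines(c(paste0(names(ct), "\t", ct),
               paste0("version\t", fit$manifest$version)),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Run the full pipeline from input files
#'
#' File-level orchestration over [prioritize_genes()]: reads a
#' STRING-style links file, derives or reads the seed list (either a plain
#' gene list, or an OBO ontology root whose term closure selects seeds
#' from an annotation table), reads optional GO/KEGG annotation tables for
#' the functional filter, runs the pipeline and writes every intermediate
#' table to `out_dir`.
#'
#' @param links_path STRING-style links file.
#' @param organism_code organism prefix filter, e.g. `"3702"`.
#' @param seed_list_path plain gene-list file of validated seeds, or
#'   `NULL` to derive seeds from the ontology.
#' @param obo_path,ontology_root,po_annotations_path OBO file, root term
#'   and gene-to-term table used to derive seeds when `seed_list_path` is
#'   `NULL`.
#' @param annotation_paths character vector of gene-to-term tables
#'   (GO/KEGG) merged into the functional-filter catalog; `NULL` skips the
#'   functional filter.
#' @param out_dir output directory for intermediate tables; `NULL` skips
#'   writing.
#' @param seed integer seed for the permutation null, forwarded to
#'   [prioritize_genes()].
#' @param ... passed on to [prioritize_genes()] (configs, thresholds).
#' @return the [prioritize_genes()] result, invisibly.
#' @export
run_pipeline <- function(links_path, organism_code = NULL,
                         seed_list_path = NULL,
                         obo_path = NULL, ontology_root = NULL,
                         po_annotations_path = NULL,
                         annotation_paths = NULL,
                         out_dir = NULL, seed = NULL, ...) {
  network <- parse_string_links(links_path, organism_code)
  if (!is.null(seed_list_path)) {
    seeds <- read_gene_list(seed_list_path)
  } else {
    if (is.null(obo_path) || is.null(ontology_root) ||
        is.null(po_annotations_path))
      stop("either seed_list_path or obo_path + ontology_root + ",
           "po_annotations_path must be given")
    ontology <- parse_obo(obo_path)
    terms <- term_closure(ontology, ontology_root)
    seeds <- seeds_from_annotations(read_annotation_table(po_annotations_path),
                                    terms)
  }
  catalog <- NULL
  if (!is.null(annotation_paths)) {
    tabs <- lapply(annotation_paths, read_annotation_table)
    merged <- list()
    for (tab in tabs) {
      for (g in names(tab)) merged[[g]] <- c(merged[[g]], tab[[g]])
    }
    catalog <- annotation_catalog(merged)
  }
  fit <- prioritize_genes(network, seeds, catalog, seed = seed, ...)
  if (!is.null(out_dir)) write_prioritization(fit, out_dir)
  invisible(fit)
}
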