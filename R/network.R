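#' Construct a weighted interaction network
#'
#' A `weighted_network` is an undirected graph over gene/protein identifiers
#' whose edges carry integer interaction scores in the STRING combined-score
#' range 150--999. Edges are stored once per unordered pair with endpoints in
#' canonical (lexicographic) order; self-edges are forbidden.
#'
#' @param from,to character vectors of edge endpoints (same length).
#' @param score integer vector of interaction scores, each in `[150, 999]`.
#' @param nodes optional character vector of node identifiers; must contain
#'   every edge endpoint. Extra entries become isolated nodes.
#' @param collapse how to resolve duplicate unordered pairs: `"max"` keeps
#'   the maximum score (STRING emits each pair in both orientations and any
#'   score asymmetry is a data defect), `"error"` fails on conflict.
#' @return object of class `weighted_network`: a list with elements
#'   `nodes` (sorted character) and `edges` (data.frame `from`, `to`,
#'   `score` with `from < to`).
#' @examples
#' net <- weighted_network(c("a", "b"), c("b", "c"), c(900L, 400L))
#' net
#' @export
weighted_network <- function(from, to, score, nodes = NULL,
                             collapse = c("max", "error")) {
  collapse <- match.arg(collapse)
  from <- as.character(from); to <- as.character(to)
  score <- as.integer(score)
  if (length(from) != length(to) || length(from) != length(score))
    stop("'from', 'to' and 'score' must have equal length")
  if (anyNA(score)) stop("edge scores must be integers")
  if (any(score < 150L | score > 999L))
    stop("edge scores must lie in [150, 999]")
  self <- from == to
  if (any(self)) {
    from <- from[!self]; to <- to[!self]; score <- score[!self]
  }
  # canonical orientation, then collapse duplicates
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  if (length(from)) {
    key <- paste(from, to, sep = "\r")
    if (anyDuplicated(key)) {
      agg_max <- tapply(score, key, max)
      if (collapse == "error" && any(tapply(score, key, min) != agg_max))
        stop("duplicate edges with conflicting scores")
      keep <- !duplicated(key)
      from <- from[keep]; to <- to[keep]
      score <- as.integer(agg_max[key[keep]])
    }
    o <- order(from, to)
    from <- from[o]; to <- to[o]; score <- score[o]
  }
  if (!is.null(nodes) && !all(c(from, to) %in% as.character(nodes)))
    stop("every edge endpoint must be a member of 'nodes'")
  all_nodes <- sort(unique(c(from, to, as.character(nodes))))
  structure(
    list(nodes = all_nodes,
         edges = data.frame(from = from, to = to, score = score,
                            stringsAsFactors = FALSE)),
    class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted interaction network\n")
  cat("  nodes:", length(x$nodes), "\n")
  cat("  undirected edges:", nrow(x$edges), "\n")
  if (nrow(x$edges)) {
    cat("  score range:", min(x$edges$score), "-", max(x$edges$score), "\n")
  }
  invisible(x)
}

#' Parse a STRING-style protein links file
#'
#' Reads a whitespace-separated `protein1 protein2 combined_score` table
#' (gzip files are read transparently), keeps only rows where **both**
#' protein identifiers carry the given organism prefix (`"<code>."`),
#' collapses the symmetric duplicate rows STRING emits into single
#' undirected edges (keeping the maximum score on conflict), and drops
#' self-pairs.
#'
#' The first line is treated as a header if it does not parse as a data row.
#' Any later malformed line (wrong field count or non-integer score) is an
#' error naming the line number.
#'
#' @param path path to the links file (plain or gzip).
#' @param organism_code organism taxon code, e.g. `"3702"` for
#'   *Arabidopsis thaliana*; `NULL` keeps all rows.
#' @return a [weighted_network()]. The attribute `"n_directed_pairs"` records
#'   the number of surviving input rows before undirected deduplication, so
#'   both the pair count and the undirected edge count are reportable.
#' @export
parse_string_links <- function(path, organism_code = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- tryCatch(readLines(con, warn = FALSE),
                    error = function(e) stop("cannot read '", path, "': ",
                                             conditionMessage(e)))
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty network after organism filter")
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  score_of <- function(p) suppressWarnings(as.integer(p[3]))
  start <- 1L
  if (nf[1] != 3L || is.na(score_of(parts[[1]]))) start <- 2L  # header row
  if (start > length(parts)) stop("empty network after organism filter")
  idx <- start:length(parts)
  bad <- idx[nf[idx] != 3L]
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], ": expected 3 fields, got ",
         nf[bad[1]])
  p1 <- vapply(parts[idx], `[`, "", 1L)
  p2 <- vapply(parts[idx], `[`, "", 2L)
  sc <- suppressWarnings(as.integer(vapply(parts[idx], `[`, "", 3L)))
  if (anyNA(sc))
    stop("malformed line ", lineno[idx[which(is.na(sc))[1]]],
         ": non-integer score")
  if (!is.null(organism_code)) {
    prefix <- paste0(organism_code, ".")
    ok <- startsWith(p1, prefix) & startsWith(p2, prefix)
    p1 <- p1[ok]; p2 <- p2[ok]; sc <- sc[ok]
  }
  ns <- p1 != p2
  p1 <- p1[ns]; p2 <- p2[ns]; sc <- sc[ns]
  if (!length(p1)) stop("empty network after organism filter")
  net <- weighted_network(p1, p2, sc)
  attr(net, "n_directed_pairs") <- length(p1)
  net
}

#' Write a network in STRING links format
#'
#' Emits the exact dialect [parse_string_links()] reads: a header line and
#' whitespace-separated `protein1 protein2 combined_score` rows, each
#' unordered pair listed in both orientations (as STRING does).
#'
#' @param network a [weighted_network()].
#' @param path output file path.
#' @param organism_code if non-`NULL`, node identifiers are prefixed with
#'   `"<code>."` unless they already carry it.
#' @param both_directions list each pair twice (a--b and b--a), mirroring
#'   STRING's symmetric rows.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(network, path, organism_code = NULL,
                               both_directions = TRUE) {
  stopifnot(inherits(network, "weighted_network"))
  e <- network$edges
  from <- e$from; to <- e$to; sc <- e$score
  if (!is.null(organism_code)) {
    prefix <- paste0(organism_code, ".")
    tag <- function(x) ifelse(startsWith(x, prefix), x, paste0(prefix, x))
    from <- tag(from); to <- tag(to)
  }
  if (both_directions) {
    tmp_from <- c(from, to); to <- c(to, from); from <- tmp_from
    sc <- c(sc, sc)
  }
  lines <- c("protein1 protein2 combined_score", paste(from, to, sc))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a seed set
#'
#' An ordered, duplicate-free list of validated gene identifiers used as the
#' restart set of the random walk.
#'
#' @param genes character vector of gene identifiers.
#' @param provenance free-text label recording where the seeds came from
#'   (e.g. the source ontology terms).
#' @return character vector of class `seed_set` with a `provenance`
#'   attribute.
#' @export
seed_set <- function(genes, provenance = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("seed set must be non-empty")
  if (anyDuplicated(genes)) genes <- unique(genes)
  structure(genes, class = "seed_set", provenance = provenance)
}

#' @export
print.seed_set <- function(x, ...) {
  cat("Seed set:", length(x), "genes")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat(" (", prov, ")", sep = "")
  cat("\n")
  cat(" ", paste(head(unclass(x), 6), collapse = ", "),
      if (length(x) > 6) "...", "\n")
  invisible(x)
}

#' Read a gene list file
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @param provenance label stored on the returned [seed_set()].
#' @return a [seed_set()].
#' @export
read_gene_list <- function(path, provenance = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  seed_set(lines, provenance = provenance)
}

#' @rdname read_gene_list
#' @param genes character vector of identifiers to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Construct an annotation catalog
#'
#' A mapping from gene identifier to a deduplicated set of term identifiers
#' (GO terms, KEGG pathways, PO terms, ...). Genes with empty term sets are
#' permitted and recorded in the `"empty_genes"` attribute.
#'
#' @param x named list: gene identifier -> character vector of terms.
#' @return object of class `annotation_catalog` (a named list of sorted
#'   unique character vectors).
#' @export
annotation_catalog <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("'x' must be a named list of term vectors")
  out <- lapply(x, function(v) sort(unique(as.character(v))))
  empty <- names(out)[lengths(out) == 0L]
  structure(out, class = "annotation_catalog", empty_genes = empty)
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("Annotation catalog:", length(x), "genes,",
      length(unique(unlist(x, use.names = FALSE))), "terms\n")
  n_empty <- length(attr(x, "empty_genes"))
  if (n_empty) cat("  genes with no annotations:", n_empty, "\n")
  invisible(x)
}

#' Read/write a two-column annotation table
#'
#' Tab-separated `gene<TAB>term` rows, multiple rows per gene; lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return an [annotation_catalog()].
#' @export
read_annotation_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty annotation table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed annotation line ", which(lengths(parts) != 2L)[1],
         ": expected 'gene<TAB>term'")
  gene <- vapply(parts, `[`, "", 1L)
  term <- vapply(parts, `[`, "", 2L)
  annotation_catalog(split(term, gene))
}

#' @rdname read_annotation_table
#' @param catalog an [annotation_catalog()] to write.
#' @export
write_annotation_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  gene <- rep(names(catalog), lengths(catalog))
  term <- unlist(catalog, use.names = FALSE)
  writeLines(paste(gene, term, sep = "\t"), path)
  invisible(path)
}

#' Derive the seed set from term annotations
#'
#' Returns every gene annotated to at least one of the given terms, exactly
#' once, sorted lexicographically. This is how the validated seed genes are
#' obtained from the fruit-related ontology term closure.
#'
#' @param catalog an [annotation_catalog()].
#' @param terms character vector of term identifiers.
#' @return a [seed_set()].
#' @export
seeds_from_annotations <- function(catalog, terms) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!length(catalog)) stop("annotation catalog is empty")
  hit <- vapply(catalog, function(v) any(v %in% terms), NA)
  genes <- sort(names(catalog)[hit])
  if (!length(genes)) stop("no seed genes for given terms")
  seed_set(genes, provenance = paste("terms:", paste(sort(terms), collapse = ",")))
}

#' Map seed genes onto network nodes
#'
#' Gene-level identifiers (e.g. `AT5G37640`) and STRING protein node
#' identifiers (e.g. `3702.AT5G37640.1`) must be reconciled before
#' propagation. Each seed is matched against the network's node identifiers
#' after configurable normalization; a gene whose multiple protein isoforms
#' are all nodes maps to all of them (its restart mass is later split
#' equally among them by [seed_vector()]).
#'
#' @param seeds a [seed_set()] (or character vector) of gene identifiers.
#' @param network a [weighted_network()].
#' @param strip_prefix,strip_suffix normalization switches, see
#'   [normalize_gene_ids()].
#' @return list with elements `mapping` (named list: seed gene -> matching
#'   node identifiers), `seeds` (a [seed_set()] of all matched node
#'   identifiers) and `unmapped` (seed genes with no matching node).
#' @export
map_seeds_to_network <- function(seeds, network,
                                 strip_prefix = TRUE, strip_suffix = TRUE) {
  stopifnot(inherits(network, "weighted_network"))
  seeds <- as.character(seeds)
  nodes <- network$nodes
  norm <- normalize_gene_ids(nodes, strip_prefix, strip_suffix)
  by_norm <- split(nodes, norm)
  mapping <- lapply(seeds, function(g) {
    if (g %in% nodes) g else by_norm[[g]] %||% character()
  })
  names(mapping) <- seeds
  unmapped <- seeds[lengths(mapping) == 0L]
  mapping <- mapping[lengths(mapping) > 0L]
  if (!length(mapping)) stop("zero seed genes mapped to network nodes")
  list(mapping = mapping,
       seeds = seed_set(unlist(mapping, use.names = FALSE),
                        provenance = attr(seeds, "provenance") %||% "mapped"),
       unmapped = unmapped)
}

#' Compare two gene sets
#'
#' Exact intersection and set differences after the same identifier
#' normalization used for seed mapping; used e.g. to measure the overlap of
#' two prioritization methods' outputs.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param strip_prefix,strip_suffix normalization switches, see
#'   [normalize_gene_ids()].
#' @return list with `shared`, `only_a`, `only_b` (sorted character vectors)
#'   and `counts` (named integer vector).
#' @export
compare_gene_sets <- function(set_a, set_b,
                              strip_prefix = TRUE, strip_suffix = TRUE) {
  a <- unique(normalize_gene_ids(as.character(set_a), strip_prefix, strip_suffix))
  b <- unique(normalize_gene_ids(as.character(set_b), strip_prefix, strip_suffix))
  shared <- sort(intersect(a, b))
  only_a <- sort(setdiff(a, b))
  only_b <- sort(setdiff(b, a))
  list(shared = shared, only_a = only_a, only_b = only_b,
       counts = c(shared = length(shared), only_a = length(only_a),
                  only_b = length(only_b)))
}
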