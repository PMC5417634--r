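#' Parse an OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas with `id:`, `name:`, `is_a:` and
#' `relationship: part_of` lines into a small ontology graph. Both `is_a`
#' and `part_of` links are kept as parent links: ontologies such as the
#' Plant Ontology attach anatomical parts (pericarp, mesocarp) to their
#' whole via `part_of`, and term closures must traverse them to recover the
#' full set of descendant terms. Obsolete terms are excluded.
#'
#' @param path path to an OBO file.
#' @return object of class `ontology_graph`: list with `terms`
#'   (data.frame `id`, `name`) and `parents` (named list: term id ->
#'   character vector of parent term ids). A stanza without an `id` is an
#'   error; a parent reference to an unknown term is dropped with a warning.
#' @export
parse_obo <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in '", path, "'")
  # stanza ends at the next stanza header ([Term], [Typedef], ...) or EOF
  headers <- which(grepl("^\\[.*\\]$", lines))
  ids <- character(); nms <- character(); obsolete <- logical()
  parents <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]
    e <- headers[headers > s]
    e <- if (length(e)) min(e) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    field <- function(key) sub(paste0("^", key, ":\\s*"), "",
                               grep(paste0("^", key, ":"), block, value = TRUE))
    id <- field("id")
    if (!length(id) || !nzchar(id[1]))
      stop("stanza ", k, " (line ", s, ") has no id")
    id <- id[1]
    name <- field("name")
    isa <- sub("\\s*!.*$", "", field("is_a"))
    rel <- field("relationship")
    partof <- sub("\\s*!.*$", "", sub("^part_of\\s+", "",
                                      grep("^part_of\\s", rel, value = TRUE)))
    obs <- any(grepl("^is_obsolete:\\s*true", block))
    ids <- c(ids, id)
    nms <- c(nms, if (length(name)) name[1] else NA_character_)
    obsolete <- c(obsolete, obs)
    parents[[id]] <- trimws(c(isa, partof))
  }
  if (anyDuplicated(ids)) stop("duplicate term id: ", ids[duplicated(ids)][1])
  keep <- !obsolete
  ids <- ids[keep]; nms <- nms[keep]
  parents <- parents[ids]
  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling)) {
    warning("dropping links to unknown parent term(s): ",
            paste(dangling, collapse = ", "))
    parents <- lapply(parents, function(p) p[p %in% ids])
  }
  g <- structure(list(terms = data.frame(id = ids, name = nms,
                                         stringsAsFactors = FALSE),
                      parents = parents),
                 class = "ontology_graph")
  assert_acyclic(g)
  g
}

# parent links must form a DAG for closures to be well-defined
assert_acyclic <- function(ontology) {
  parents <- ontology$parents
  indeg <- vapply(parents, length, 0L)  # number of parents per term
  order_done <- 0L
  children <- term_children(ontology)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order_done <- order_done + 1L
    for (ch in children[[t]] %||% character()) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (order_done != length(parents))
    stop("ontology parent links contain a cycle")
  invisible(TRUE)
}

term_children <- function(ontology) {
  parents <- ontology$parents
  child <- rep(names(parents), lengths(parents))
  parent <- unlist(parents, use.names = FALSE)
  split(child, factor(parent, levels = names(parents)))
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph:", nrow(x$terms), "terms,",
      sum(lengths(x$parents)), "parent links\n")
  invisible(x)
}

#' Descendant closure of an ontology term
#'
#' Returns the root term plus every term reachable from it by reversed
#' parent links (children, grandchildren, ...). This is how the set of
#' fruit-related terms is derived from the "fruit" root term.
#'
#' @param ontology an [parse_obo()] result.
#' @param root term identifier present in the ontology.
#' @return sorted character vector of term identifiers, always containing
#'   `root`.
#' @export
term_closure <- function(ontology, root) {
  stopifnot(inherits(ontology, "ontology_graph"))
  if (!root %in% ontology$terms$id) stop("unknown root term: ", root)
  children <- term_children(ontology)
  seen <- character()
  queue <- root
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, children[[t]] %||% character())
  }
  sort(seen)
}

#' Ancestor closure of annotations
#'
#' Optionally propagates each gene's terms up the ontology (every ancestor
#' of an annotated term is added) before annotation vectors are built.
#'
#' @param catalog an [annotation_catalog()].
#' @param ontology an [parse_obo()] result covering the catalog's terms;
#'   terms absent from the ontology are kept unchanged.
#' @return an [annotation_catalog()] with ancestors added.
#' @export
annotate_with_ancestors <- function(catalog, ontology) {
  stopifnot(inherits(catalog, "annotation_catalog"),
            inherits(ontology, "ontology_graph"))
  parents <- ontology$parents
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    ps <- parents[[t]] %||% character()
    out <- unique(c(ps, unlist(lapply(ps, ancestors), use.names = FALSE)))
    anc_cache[[t]] <- out
    out
  }
  out <- lapply(catalog, function(terms) {
    known <- terms[terms %in% names(parents)]
    unique(c(terms, unlist(lapply(known, ancestors), use.names = FALSE)))
  })
  annotation_catalog(out)
}
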