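#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats phyper runif setNames
#' @importFrom utils head write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this helper so that results
# are reproducible from a single integer seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named substream (edges, scores, annotations,
# split, ...), kept within 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offsets <- c(edges = 1L, scores = 2L, annotations = 3L, split = 4L,
               null_sets = 5L, observed = 6L)
  k <- offsets[[stream]]
  (as.integer(seed) %% 2146483L) * 1000L + k
}

#' Normalize gene/protein identifiers
#'
#' Applies the two-step identifier normalization used when joining gene-level
#' identifiers (e.g. `AT5G37640`) with STRING protein node identifiers
#' (e.g. `3702.AT5G37640.1`): optionally strip a numeric organism prefix
#' (`"NNNN."`) and a trailing numeric transcript/isoform suffix (`".k"`).
#'
#' @param ids character vector of identifiers.
#' @param strip_prefix drop a leading `"<digits>."` organism prefix.
#' @param strip_suffix drop a trailing `".<digits>"` transcript suffix.
#' @return character vector of normalized identifiers.
#' @examples
#' normalize_gene_ids("3702.AT1G01010.1")
#' @export
normalize_gene_ids <- function(ids, strip_prefix = TRUE, strip_suffix = TRUE) {
  out <- as.character(ids)
  if (strip_prefix) out <- sub("^[0-9]+\\.", "", out)
  if (strip_suffix) out <- sub("\\.[0-9]+$", "", out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
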