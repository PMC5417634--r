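# Shared fixture builders. Everything is generated in code; no binary data.

# tiny STRING-style links file; `lines` given verbatim
write_links_file <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  if (header) lines <- c("protein1 protein2 combined_score", lines)
  writeLines(lines, path)
  path
}

# linear is_a chain T1 <- T2 <- ... <- Tn (T1 is the root)
write_chain_obo <- function(n = 5) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  stanzas <- c("format-version: 1.2", "")
  for (k in seq_len(n)) {
    stanzas <- c(stanzas, "[Term]",
                 sprintf("id: T:%03d", k),
                 sprintf("name: term %d", k),
                 if (k > 1) sprintf("is_a: T:%03d ! term %d", k - 1, k - 1),
                 "")
  }
  writeLines(stanzas, path)
  path
}

# small random network via the planted-partition generator (homogeneous
# when p_in == p_out)
random_network <- function(n = 50, p = 0.1, seed = 1) {
  spec <- planted_module_spec(
    n_nodes = n, module_size = max(2, floor(n / 10)),
    p_in = p, p_out = p,
    score_in = c(150L, 999L), score_out = c(150L, 999L),
    rng_seed = seed)
  generate_planted_network(spec)$network
}

# strong-signal study conditions (the benchmark defaults)
strong_spec <- function(seed) planted_module_spec(rng_seed = seed)

# independent brute-force oracle for the hypergeometric upper tail:
# probability that a uniform draw of `n` genes from `N` contains at least
# `k` of the `K` term-annotated genes, by enumeration of all draws
hyper_tail_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}
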