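test_that("degenerate probabilities produce a clean planted clique", {
  spec <- planted_module_spec(n_nodes = 20, module_size = 5, p_in = 1,
                              p_out = 0, rng_seed = 1)
  out <- generate_planted_network(spec)
  expect_length(out$module, 5)
  expect_equal(nrow(out$network$edges), choose(5, 2))
  expect_true(all(out$network$edges$from %in% out$module))
  expect_true(all(out$network$edges$score >= 900 &
                    out$network$edges$score <= 999))
  expect_length(out$network$nodes, 20)  # isolated background nodes kept
})

test_that("edge counts match their binomial expectations", {
  spec <- planted_module_spec(n_nodes = 200, module_size = 20, p_in = 0.5,
                              p_out = 0.02, rng_seed = 8)
  out <- generate_planted_network(spec)
  e <- out$network$edges
  in_mod <- e$from %in% out$module & e$to %in% out$module
  n_pairs <- choose(20, 2)
  expect_lt(abs(sum(in_mod) - 0.5 * n_pairs),
            4 * sqrt(n_pairs * 0.5 * 0.5))
  n_bg_pairs <- choose(200, 2) - n_pairs
  expect_lt(abs(sum(!in_mod) - 0.02 * n_bg_pairs),
            4 * sqrt(n_bg_pairs * 0.02 * 0.98))
  # same seed, same network; different seed, different network
  again <- generate_planted_network(spec)
  expect_identical(out$network$edges, again$network$edges)
  other <- generate_planted_network(planted_module_spec(
    n_nodes = 200, module_size = 20, p_in = 0.5, p_out = 0.02,
    rng_seed = 9))
  expect_false(identical(out$network$edges, other$network$edges))
})

test_that("annotation sharing rates hit their expectations", {
  spec <- planted_module_spec(n_nodes = 200, module_size = 40,
                              share_in = 0.9, share_out = 0.05,
                              n_terms = 60, n_module_terms = 10,
                              background_rate = 0.05, rng_seed = 5)
  module <- sprintf("g%04d", 1:40)
  catl <- generate_annotations(spec, module)
  n_mod_terms <- function(g) sum(startsWith(catl[[g]], "MT:"))
  mod_counts <- vapply(module, n_mod_terms, 0)
  bg <- setdiff(names(catl), module)
  bg_counts <- vapply(bg, n_mod_terms, 0)
  # module genes: 10 * 0.9 = 9 module terms on average; background 0.5
  expect_lt(abs(mean(mod_counts) - 9), 4 * sqrt(10 * 0.9 * 0.1 / 40))
  expect_lt(abs(mean(bg_counts) - 0.5), 4 * sqrt(10 * 0.05 * 0.95 / 160))
  # forced sharing: every module gene carries every module term
  full <- generate_annotations(planted_module_spec(
    n_nodes = 50, module_size = 10, share_in = 1, share_out = 0,
    background_rate = 0, rng_seed = 2), sprintf("g%04d", 1:10))
  V <- build_annotation_vectors(full, sprintf("g%04d", 1:10))
  expect_equal(unname(V[1, ]), unname(V[2, ]))
  expect_equal(max_function_score("g0001", "g0002", V)[["g0001"]], 1)
})

test_that("seed splitting follows the floor rule and is reproducible", {
  module <- sprintf("m%02d", 1:20)
  sp <- split_seeds(module, 0.5, rng_seed = 3)
  expect_length(sp$seeds, 10)
  expect_length(sp$held_out, 10)
  expect_setequal(c(unclass(sp$seeds), sp$held_out), module)
  sp95 <- split_seeds(module, 0.95, rng_seed = 3)
  expect_length(sp95$seeds, 19)
  expect_length(sp95$held_out, 1)
  expect_identical(split_seeds(module, 0.5, rng_seed = 3), sp)
  expect_error(split_seeds(module[1:2], 0.4, rng_seed = 1), "empty part")
})

test_that("recovery metrics follow their definitions", {
  held <- c("a", "b", "e")
  rec <- evaluate_recovery(c("a", "b", "c", "d"), held)
  expect_equal(rec$precision, 0.5)
  expect_equal(rec$recall, 2 / 3)
  perfect <- evaluate_recovery(held, held)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  none <- evaluate_recovery(character(), held)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_error(evaluate_recovery("a", character()), "empty")
  ranked <- evaluate_recovery("a", held, ranking = c("x", "a", "b"))
  expect_equal(ranked$ranks[["a"]], 2)
})

test_that("held-out module genes outrank background genes in propagation", {
  for (s in c(1, 4)) {
    spec <- strong_spec(s)
    sim <- generate_planted_network(spec)
    split <- split_seeds(sim$module, spec$seed_fraction, rng_seed = s)
    M <- transition_matrix(sim$network)
    p <- run_rwr(M, seed_vector(unclass(split$seeds), rownames(M)))
    bg <- setdiff(sim$network$nodes, sim$module)
    expect_gt(median(p[split$held_out]), median(p[bg]))
  }
})

test_that("with no planted signal putative genes show no module preference", {
  spec <- planted_module_spec(p_in = 0.05, p_out = 0.05,
                              score_in = c(150L, 999L),
                              score_out = c(150L, 999L),
                              share_in = 0.05, share_out = 0.05,
                              rng_seed = 6)
  sim <- generate_planted_network(spec)
  split <- split_seeds(sim$module, spec$seed_fraction, rng_seed = 6)
  catl <- generate_annotations(spec, sim$module)
  fit <- prioritize_genes(sim$network, split$seeds, catl,
                          perm = permutation_config(n_sets = 100,
                                                    rng_seed = 6))
  non_seed <- setdiff(sim$network$nodes, unclass(split$seeds))
  bg_fraction <- length(split$held_out) / length(non_seed)
  hits <- length(intersect(fit$putative, split$held_out))
  if (length(fit$putative)) {
    bt <- binom.test(hits, length(fit$putative), bg_fraction)
    expect_gt(bt$p.value, 0.01)
  } else {
    expect_length(fit$putative, 0)  # nothing selected at all: consistent
  }
})
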