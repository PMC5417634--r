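test_that("transition matrix columns are stochastic with scores as weights", {
  net <- weighted_network(c("A", "A"), c("B", "C"), c(150L, 450L))
  M <- transition_matrix(net)
  expect_equal(as.numeric(Matrix::colSums(M)), rep(1, 3), tolerance = 1e-12)
  # column A splits 150/(150+450) = 0.25 to B, 0.75 to C
  expect_equal(M["B", "A"], 0.25)
  expect_equal(M["C", "A"], 0.75)
  # single-edge columns are unit vectors toward the other node
  expect_equal(M["A", "B"], 1)
})

test_that("isolated nodes receive a unit self-loop", {
  net <- weighted_network("A", "B", 900L, nodes = c("A", "B", "D"))
  M <- transition_matrix(net)
  expect_equal(M["D", "D"], 1)
  expect_equal(as.numeric(Matrix::colSums(M)), rep(1, 3))
})

test_that("initial vector spreads unit mass over seeds and isoform groups", {
  nodes <- c("a", "b", "c", "d")
  p0 <- seed_vector(c("a", "b", "c", "d"), nodes)
  expect_equal(unname(p0), rep(0.25, 4))
  expect_equal(sum(p0), 1)
  p1 <- seed_vector("a", nodes)
  expect_equal(p1[["a"]], 1)
  # a gene with two isoform nodes splits its share equally
  p2 <- seed_vector(list(g1 = c("a", "b"), g2 = "c"), nodes)
  expect_equal(unname(p2), c(0.25, 0.25, 0.5, 0))
  expect_error(seed_vector(character(), nodes), "empty seed")
  expect_error(seed_vector("zz", nodes), "not in network")
})

test_that("two-node propagation reaches the closed-form stationary point", {
  # p = c (I - (1-c) M)^{-1} p0 solved by hand: (5/6, 1/6) at c = 0.8
  net <- weighted_network("a", "b", 900L)
  M <- transition_matrix(net)
  p0 <- seed_vector("a", rownames(M))
  p <- run_rwr(M, p0, rwr_config(tolerance = 1e-11))
  expect_equal(p[["a"]], 5 / 6, tolerance = 1e-9)
  expect_equal(p[["b"]], 1 / 6, tolerance = 1e-9)
  expect_true(attr(p, "converged"))
  # and the dense-solve oracle lands on the same point
  pd <- solve_rwr_direct(M, p0)
  expect_equal(pd[["a"]], 5 / 6, tolerance = 1e-12)
})

test_that("restart probability one returns the initial vector", {
  net <- random_network(20, 0.2, seed = 2)
  M <- transition_matrix(net)
  p0 <- seed_vector(net$nodes[1:3], rownames(M))
  p <- run_rwr(M, p0, rwr_config(restart_prob = 1))
  expect_equal(as.numeric(p), unname(p0))
  expect_equal(unname(solve_rwr_direct(M, p0, 1)), unname(p0))
})

test_that("seeding every node of a symmetric complete graph stays uniform", {
  n <- 6
  pairs <- utils::combn(n, 2)
  net <- weighted_network(letters[pairs[1, ]], letters[pairs[2, ]],
                          rep(500L, ncol(pairs)))
  M <- transition_matrix(net)
  p <- run_rwr(M, seed_vector(net$nodes, rownames(M)))
  expect_equal(as.numeric(p), rep(1 / n, n), tolerance = 1e-9)
})

test_that("iterative propagation matches the dense-solve oracle on random graphs", {
  for (s in 1:5) {
    net <- random_network(50, 0.1, seed = s)
    M <- transition_matrix(net)
    seeds <- with_seed(s, sample(net$nodes, 5))
    p0 <- seed_vector(seeds, rownames(M))
    p <- run_rwr(M, p0, rwr_config(tolerance = 1e-9))
    pd <- solve_rwr_direct(M, p0)
    expect_lt(sum(abs(p - pd)), 1e-8)
  }
})

test_that("propagation conserves probability mass at every iterate", {
  net <- random_network(40, 0.15, seed = 9)
  M <- transition_matrix(net)
  p0 <- seed_vector(net$nodes[1:4], rownames(M))
  cfg <- rwr_config()
  # walk the update by hand to inspect intermediate iterates
  p <- p0
  for (i in 1:30) {
    p <- (1 - cfg$restart_prob) * as.numeric(M %*% p) +
      cfg$restart_prob * p0
    expect_lt(abs(sum(p) - 1), 1e-9)
  }
  expect_lt(abs(sum(run_rwr(M, p0, cfg)) - 1), 1e-9)
})

test_that("seed-set mass is non-decreasing in the restart probability", {
  for (s in c(3, 8)) {
    net <- random_network(60, 0.1, seed = s)
    M <- transition_matrix(net)
    seeds <- with_seed(s + 100, sample(net$nodes, 6))
    p0 <- seed_vector(seeds, rownames(M))
    mass <- vapply(c(0.1, 0.5, 0.8, 0.95), function(cc) {
      sum(run_rwr(M, p0, rwr_config(restart_prob = cc,
                                    tolerance = 1e-9))[seeds])
    }, 0)
    expect_true(all(diff(mass) >= -1e-9))
  }
})

test_that("the literal update rule diverges on a connected regular graph", {
  # 6-cycle, equal scores: the un-damped update adds c of restart mass
  # every step, so the L1 norm of the iterate grows without bound
  net <- weighted_network(letters[1:6], letters[c(2:6, 1)], rep(500L, 6))
  M <- transition_matrix(net)
  p0 <- seed_vector("a", rownames(M))
  err <- tryCatch(
    run_rwr(M, p0, rwr_config(update_rule = "literal", max_iter = 300)),
    fruitwalk_nonconvergence = function(e) e)
  expect_s3_class(err, "fruitwalk_nonconvergence")
  expect_gt(err$last_norm, 10)   # mass not conserved: far above 1
  expect_gt(err$gap, rwr_config()$tolerance)
})

test_that("relabeling nodes permutes the probability vector identically", {
  net <- random_network(30, 0.15, seed = 4)
  M <- transition_matrix(net)
  seeds <- net$nodes[1:3]
  p <- run_rwr(M, seed_vector(seeds, rownames(M)), rwr_config(tolerance = 1e-9))
  relabel <- setNames(sprintf("z%03d", rev(seq_along(net$nodes))), net$nodes)
  net2 <- weighted_network(relabel[net$edges$from], relabel[net$edges$to],
                           net$edges$score, nodes = unname(relabel))
  M2 <- transition_matrix(net2)
  p2 <- run_rwr(M2, seed_vector(unname(relabel[seeds]), rownames(M2)),
                rwr_config(tolerance = 1e-9))
  expect_equal(unname(p2[relabel[names(p)]]), unname(unclass(p)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gene selection is strict at the threshold and excludes seeds", {
  p <- c(s = 0.9, g1 = 2e-5, g2 = 1e-5, g3 = 1e-6)
  sel <- select_rwr_genes(p, "s")
  expect_equal(sel$gene, "g1")  # g2 equals the cutoff, g3 below, s a seed
  all_pos <- select_rwr_genes(p, "s", rwr_config(threshold = 0))
  expect_equal(all_pos$gene, c("g1", "g2", "g3"))
  # descending probability with lexicographic tie-break
  p2 <- c(s = 0.5, b = 0.1, a = 0.1, c = 0.2)
  expect_equal(select_rwr_genes(p2, "s")$gene, c("c", "a", "b"))
})
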