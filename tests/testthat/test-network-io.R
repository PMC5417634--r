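test_that("STRING links parsing collapses symmetric rows into undirected edges", {
  path <- write_links_file(c("3702.A 3702.B 900",
                             "3702.B 3702.A 900",
                             "3702.A 3702.C 300",
                             "3702.C 3702.A 300"))
  net <- parse_string_links(path, "3702")
  expect_s3_class(net, "weighted_network")
  expect_setequal(net$nodes, c("3702.A", "3702.B", "3702.C"))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(attr(net, "n_directed_pairs"), 4L)
  # undirected edge count is at most half the directed pair count
  expect_lte(nrow(net$edges), attr(net, "n_directed_pairs") / 2)
  expect_equal(net$edges$score[net$edges$from == "3702.A" &
                                 net$edges$to == "3702.B"], 900L)
})

test_that("organism filter keeps only rows where both ids carry the prefix", {
  path <- write_links_file(c("3702.A 3702.B 500",
                             "9606.X 9606.Y 700",
                             "3702.A 9606.Y 800"))
  net <- parse_string_links(path, "3702")
  expect_equal(net$nodes, c("3702.A", "3702.B"))
  expect_error(parse_string_links(path, "1234"),
               "empty network after organism filter")
})

test_that("malformed lines are reported with their line number", {
  path <- write_links_file(c("3702.A 3702.B 500", "3702.A 3702.C"))
  expect_error(parse_string_links(path, "3702"), "line 3")
  path2 <- write_links_file(c("3702.A 3702.B notanumber"))
  expect_error(parse_string_links(path2, "3702"), "line 2.*non-integer")
})

test_that("duplicate pairs with conflicting scores keep the maximum", {
  path <- write_links_file(c("3702.A 3702.B 500",
                             "3702.B 3702.A 650",
                             "3702.A 3702.A 900"))  # self-pair dropped
  net <- parse_string_links(path, "3702")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$score, 650L)
})

test_that("parsing is idempotent on its own re-serialized output", {
  spec <- planted_module_spec(n_nodes = 40, module_size = 6, rng_seed = 5)
  net <- generate_planted_network(spec)$network
  path <- withr::local_tempfile(fileext = ".txt")
  write_string_links(net, path, organism_code = "3702")
  reread <- parse_string_links(path, "3702")
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_string_links(reread, path2)
  reread2 <- parse_string_links(path2)
  expect_equal(reread$edges, reread2$edges)
  # and the synthetic edges survive the round trip (modulo the prefix)
  expect_equal(normalize_gene_ids(reread$edges$from, strip_suffix = FALSE),
               net$edges$from[net$edges$from %in%
                                normalize_gene_ids(reread$edges$from,
                                                   strip_suffix = FALSE)])
  expect_equal(nrow(reread$edges), nrow(net$edges))
})

test_that("weighted_network enforces score range and forbids self-edges", {
  expect_error(weighted_network("a", "b", 100L), "150")
  expect_error(weighted_network("a", "b", 1000L), "150|999")
  net <- weighted_network(c("a", "a"), c("a", "b"), c(900L, 900L))
  expect_equal(nrow(net$edges), 1L)  # self-edge silently dropped
  expect_error(weighted_network("a", "b", 900L, nodes = "a"),
               "member of 'nodes'")
})

test_that("gene lists and annotation tables round-trip with comments ignored", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# validated genes", "AT1G01010", "", "AT2G02020"), path)
  seeds <- read_gene_list(path)
  expect_s3_class(seeds, "seed_set")
  expect_equal(unclass(seeds), c("AT1G01010", "AT2G02020"),
               ignore_attr = TRUE)

  cat0 <- annotation_catalog(list(g1 = c("T1", "T1", "T3"), g2 = "T2",
                                  g3 = character()))
  expect_equal(cat0$g1, c("T1", "T3"))
  expect_equal(attr(cat0, "empty_genes"), "g3")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(cat0, path2)
  back <- read_annotation_table(path2)
  expect_equal(back$g1, cat0$g1)
  expect_equal(back$g2, cat0$g2)
})

test_that("seeds are derived from term annotations sorted and deduplicated", {
  catl <- annotation_catalog(list(g1 = "T1", g2 = "T2", g3 = c("T1", "T3")))
  seeds <- seeds_from_annotations(catl, "T1")
  expect_equal(unclass(seeds), c("g1", "g3"), ignore_attr = TRUE)
  expect_error(seeds_from_annotations(catl, "T9"),
               "no seed genes for given terms")
})

test_that("seed mapping reconciles gene ids with prefixed isoform node ids", {
  net <- weighted_network(c("3702.AT1G01010.1", "3702.AT1G01010.2"),
                          c("3702.AT2G02020.1", "3702.AT2G02020.1"),
                          c(900L, 800L))
  m <- map_seeds_to_network(seed_set(c("AT1G01010", "XYZ")), net)
  expect_equal(sort(m$mapping$AT1G01010),
               c("3702.AT1G01010.1", "3702.AT1G01010.2"))
  expect_equal(m$unmapped, "XYZ")
  # already-matching ids map to themselves
  m2 <- map_seeds_to_network(seed_set("3702.AT1G01010.1"), net)
  expect_equal(m2$mapping[["3702.AT1G01010.1"]], "3702.AT1G01010.1")
  expect_error(map_seeds_to_network(seed_set("NOPE"), net), "zero seed")
})

test_that("gene-set comparison reports shared and exclusive members", {
  cmp <- compare_gene_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(cmp$counts,
               c(shared = 2L, only_a = 1L, only_b = 1L))
  same <- compare_gene_sets(c("a", "b"), c("b", "a"))
  expect_equal(same$shared, c("a", "b"))
  expect_length(same$only_a, 0)
})
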