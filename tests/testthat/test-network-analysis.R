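test_that("edge-list reader merges reversed duplicates and validates scores", {
  path <- withr::local_tempfile(lines = c(
    "protein1\tprotein2\tcombined_score",
    "A\tB\t0.9", "B\tA\t0.7", "B\tC\t0.4"), fileext = ".tsv")
  g <- read_edge_list(path)
  expect_length(graph_nodes(g), 3)
  edges <- graph_edges(g)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$combined_score[edges$from == "A" & edges$to == "B"], 0.9)

  bad <- withr::local_tempfile(lines = c(
    "protein1\tprotein2\tcombined_score", "A\tB\t1.7"), fileext = ".tsv")
  expect_error(read_edge_list(bad), class = "enorthern_validation_error")

  empty <- withr::local_tempfile(lines = "protein1\tprotein2\tcombined_score",
                                 fileext = ".tsv")
  g0 <- read_edge_list(empty, nodes = c("X", "Y", "Z"))
  expect_equal(isolated_nodes(g0), c("X", "Y", "Z"))
})

test_that("purging to a gene set keeps missing genes as isolated nodes", {
  g <- interaction_graph(tibble::tibble(
    from = c("A", "C"), to = c("B", "D"), combined_score = c(0.9, 0.8)))
  sub <- purge_to_gene_set(g, c("A", "B", "C"))
  expect_setequal(graph_nodes(sub), c("A", "B", "C"))
  expect_equal(nrow(graph_edges(sub)), 1)
  expect_equal(isolated_nodes(sub), "C")

  disjoint <- purge_to_gene_set(g, c("X", "Y"))
  expect_equal(nrow(graph_edges(disjoint)), 0)
  expect_equal(isolated_nodes(disjoint), c("X", "Y"))
  expect_equal(attr(disjoint, "missing_genes"), c("X", "Y"))

  expect_error(purge_to_gene_set(g, character()), class = "enorthern_validation_error")

  # identity and idempotence
  all_nodes <- graph_nodes(g)
  same <- purge_to_gene_set(g, all_nodes)
  expect_equal(graph_edges(same), graph_edges(g))
  twice <- purge_to_gene_set(purge_to_gene_set(g, c("A", "B")), c("A", "B"))
  expect_equal(graph_edges(twice), graph_edges(purge_to_gene_set(g, c("A", "B"))))
})

test_that("isolated-node detection handles complete and edgeless graphs", {
  k4 <- t(utils::combn(c("A", "B", "C", "D"), 2))
  g <- interaction_graph(tibble::tibble(from = k4[, 1], to = k4[, 2],
                                        combined_score = 0.5))
  expect_length(isolated_nodes(g), 0)
  edgeless <- interaction_graph(nodes = sprintf("N%d", 1:5))
  expect_length(isolated_nodes(edgeless), 5)
})

test_that("degree ranking filters by score and breaks ties alphabetically", {
  leaves <- sprintf("L%d", 1:6)
  star <- interaction_graph(tibble::tibble(from = "H", to = leaves,
                                           combined_score = 0.9))
  rk <- degree_ranking(star, min_score = 0.4)
  expect_equal(rk$gene[1], "H")
  expect_equal(rk$degree[1], 6L)
  expect_equal(rk$gene[-1], sort(leaves))  # all tied at degree 1

  all_low <- interaction_graph(tibble::tibble(from = "A", to = "B",
                                              combined_score = 0.5))
  expect_true(all(degree_ranking(all_low, min_score = 1.0)$degree == 0))
})

test_that("degree ranking and components agree with brute-force oracles", {
  withr::local_seed(7)
  for (i in 1:20) {
    rg <- random_edge_table(10, 0.3)
    g <- interaction_graph(rg$edges, nodes = rg$nodes)
    rk <- degree_ranking(g, min_score = 0)
    want <- oracle_degrees(rg$edges, rg$nodes)
    expect_equal(setNames(rk$degree, rk$gene)[rg$nodes], want)
    # ordering contract: descending degree, alphabetical within ties
    expect_true(all(diff(rk$degree) <= 0))

    comp <- connected_components(g)
    expect_equal(comp, oracle_components(rg$edges, rg$nodes))
    # handshake lemma after score filtering
    rk5 <- degree_ranking(g, min_score = 0.5)
    expect_equal(sum(rk5$degree), 2 * sum(rg$edges$combined_score >= 0.5))
  }
})

test_that("channel filtering keeps nodes and validates the channel name", {
  g <- interaction_graph(tibble::tibble(
    from = c("A", "B"), to = c("B", "C"),
    coexpression = c(0.0, 0.8), combined_score = c(0.9, 0.9)))
  sub <- channel_subgraph(g, "coexpression", 0.1)
  expect_setequal(graph_nodes(sub), c("A", "B", "C"))
  expect_equal(nrow(graph_edges(sub)), 1)

  ident <- channel_subgraph(g, "coexpression", 0)
  expect_equal(nrow(graph_edges(ident)), 2)
  expect_equal(isolated_nodes(ident), isolated_nodes(g))

  expect_error(channel_subgraph(g, "homology", 0.4),
               class = "enorthern_validation_error")
})

test_that("components partition small graphs as expected", {
  tri2 <- interaction_graph(tibble::tibble(
    from = c("A", "B", "C", "X", "Y", "Z"),
    to = c("B", "C", "A", "Y", "Z", "X"),
    combined_score = 0.6))
  comp <- connected_components(tri2)
  expect_equal(lengths(comp), c(3L, 3L))
  edgeless <- interaction_graph(nodes = sprintf("N%d", 1:4))
  expect_equal(lengths(connected_components(edgeless)), rep(1L, 4))
})

test_that("synthetic demonstration network reproduces the qualitative findings", {
  # Illustrative fixture only: topology hand-written, not a database export.
  g <- read_edge_list(enorthern_example("string_fixture_synthetic.tsv"))
  res <- run_enorthern(table2_fixture())
  up <- res$gene[res$status == "UP"]
  sub <- purge_to_gene_set(g, up)
  expect_setequal(graph_nodes(sub), up)
  expect_equal(isolated_nodes(sub), c("SPTLC1", "XDH"))
  hubs <- head(degree_ranking(g, min_score = 0.4)$gene, 5)
  expect_setequal(hubs, c("PPARG", "FASN", "SREBF1", "SREBF2", "ACSS2"))
})
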