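test_that("network loading dedups, drops loops and reports counts", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tA", "A\tpp\tA", "B\tpp\tC"), path)
  expect_message(g <- load_network(path), "2 nodes|3 nodes")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_false(igraph::any_loop(g))
  # idempotence: re-cleaning the cleaned edge list changes nothing
  el <- igraph::as_edgelist(g)
  g2 <- suppressMessages(load_network(data.frame(from = el[, 1],
                                                 to = el[, 2])))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
})

test_that("SIF with Windows line endings parses identically", {
  p1 <- withr::local_tempfile(fileext = ".sif")
  p2 <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tC"), p1)
  writeLines(paste0(c("A\tpp\tB", "B\tpp\tC"), "\r"), p2, sep = "\n")
  expect_identical(read_sif(p1), read_sif(p2))
})

test_that("malformed SIF lines are reported with line numbers", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "oops"), path)
  expect_error(read_sif(path), "line.*2")
})

test_that("the synthetic two-clique graph loads with 16 edges", {
  g <- two_clique_graph()
  path <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, path)
  g2 <- suppressMessages(load_network(path))
  expect_equal(igraph::ecount(g2), choose(5, 2) + choose(4, 2))
})

test_that("largest component selection is deterministic", {
  el <- rbind(c("A1", "A2"), c("A2", "A3"), c("A3", "A4"), c("A4", "A5"),
              c("Z1", "Z2"), c("Z2", "Z3"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, sprintf("A%d", 1:5))
  # connected input is the identity
  g2 <- two_clique_graph()
  sub <- igraph::induced_subgraph(g2, sprintf("A%d", 1:5))
  expect_equal(igraph::vcount(largest_component(sub)), 5)
  # equal sizes: the component holding the lexicographic minimum wins
  el3 <- rbind(c("B1", "B2"), c("B2", "B3"),
               c("A1", "A9"), c("A9", "A5"))
  g3 <- igraph::graph_from_edgelist(el3, directed = FALSE)
  expect_true("A1" %in% igraph::V(largest_component(g3))$name)
})

test_that("core numbers match the minimum-degree peeling oracle", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(core_numbers(tri)), c(2, 2, 2))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- sprintf("s%d", 1:5)
  expect_equal(unname(core_numbers(star)), rep(1, 5))
  for (seed in 1:40) {
    adj <- random_adj(8, 0.35, seed)
    g <- adj_to_graph(adj)
    expect_equal(core_numbers(g)[rownames(adj)], bf_core_numbers(adj))
  }
})

test_that("vertex weights follow the closed-neighborhood core definition", {
  # isolated edge: closed neighborhoods are K2 -> k=1, density 1, weight 1
  e <- igraph::graph_from_edgelist(matrix(c("X", "Y"), 1), directed = FALSE)
  expect_equal(unname(mcode_vertex_weights(e)), c(1, 1))
  # 4-clique vertex: closed neighborhood K4 -> k=3, density 1, weight 3
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- sprintf("v%d", 1:4)
  expect_equal(unname(mcode_vertex_weights(k4)), rep(3, 4))
  # invariance under relabeling
  adj <- random_adj(9, 0.4, 99)
  w1 <- mcode_vertex_weights(adj_to_graph(adj))
  perm <- c(3, 1, 2, 9, 5, 4, 8, 6, 7)
  adj2 <- adj[perm, perm]
  w2 <- mcode_vertex_weights(adj_to_graph(adj2))
  expect_equal(w2[names(w1)], w1)
})

test_that("complexes on the two-clique graph score 5 and 4", {
  cx <- mcode_complexes(two_clique_graph())
  expect_length(cx, 2)
  expect_equal(cx[[1]]$score, 5)
  expect_setequal(cx[[1]]$members, sprintf("A%d", 1:5))
  expect_equal(cx[[2]]$score, 4)
  expect_setequal(cx[[2]]$members, sprintf("B%d", 1:4))
  # stored score equals density x size recomputed from members
  for (c in cx) {
    sub <- igraph::induced_subgraph(two_clique_graph(), c$members)
    dens <- 2 * igraph::ecount(sub) /
      (igraph::vcount(sub) * (igraph::vcount(sub) - 1))
    expect_equal(c$score, dens * length(c$members), tolerance = 1e-12)
  }
})

test_that("an all-filtered graph yields an empty complex list", {
  ring <- igraph::make_ring(6)   # density 2/5, score 2.4/... low cores
  igraph::V(ring)$name <- sprintf("r%d", 1:6)
  cx <- mcode_complexes(ring, mcode_params(score_threshold = 10))
  expect_length(cx, 0)
})

test_that("complex members induce connected subgraphs after haircut", {
  for (seed in 1:30) {
    adj <- random_adj(12, 0.3, 200 + seed)
    g <- adj_to_graph(adj)
    for (cx in mcode_complexes(g, mcode_params(score_threshold = 0))) {
      sub <- igraph::induced_subgraph(g, cx$members)
      expect_true(igraph::is_connected(sub))
      expect_equal(cx$score,
                   (2 * igraph::ecount(sub) /
                      (igraph::vcount(sub) * (igraph::vcount(sub) - 1))) *
                     igraph::vcount(sub),
                   tolerance = 1e-12)
    }
  }
})

compare_complexes <- function(mine, oracle, label) {
  expect_equal(length(mine), length(oracle), info = label)
  for (i in seq_along(mine)) {
    expect_identical(mine[[i]]$members, oracle[[i]]$members, info = label)
    expect_equal(mine[[i]]$score, oracle[[i]]$score, tolerance = 1e-12,
                 info = label)
  }
}

test_that("weights, cores and complexes match the brute-force oracle", {
  params <- mcode_params(score_threshold = 0)
  for (seed in 1:60) {
    n <- sample(c(6, 8, 10), 1)
    adj <- random_adj(n, stats::runif(1, 0.2, 0.6), 300 + seed)
    g <- adj_to_graph(adj)
    expect_equal(core_numbers(g)[rownames(adj)], bf_core_numbers(adj),
                 info = seed)
    expect_equal(mcode_vertex_weights(g)[rownames(adj)],
                 bf_vertex_weights(adj), info = seed)
    compare_complexes(mcode_complexes(g, params),
                      bf_mcode(adj, score_threshold = 0), seed)
  }
})

test_that("driver mapping annotates modules and flags the unassigned", {
  g <- two_clique_graph()
  modules <- c(A1 = 1L, A2 = 1L, A3 = 1L, A4 = 1L, A5 = 1L,
               B1 = 2L, B2 = 2L, B3 = 2L, B4 = 2L)
  genes <- data.frame(
    gene = c("A1", "B2", "ZZ"), n_rds_called = c(5L, 2L, 3L),
    module = c(1L, 2L, NA), stringsAsFactors = FALSE)
  rb <- structure(list(genes = genes,
                       modules = data.frame(module = 1:2,
                                            n_rds_hit = c(5L, 2L),
                                            robust = c(TRUE, FALSE),
                                            driver_genes = c("A1", "B2"))),
                  class = "robustness")
  expect_message(out <- map_drivers(g, modules, rb), "ZZ")
  expect_equal(out$missing_drivers, "ZZ")
  v <- igraph::V(out$graph)
  expect_true(v["A1"]$driver)
  expect_equal(v["A1"]$module, 1)
  expect_equal(v["A1"]$degree, 4)
  expect_true("unassigned" %in% out$report$module)
  expect_equal(out$report$gene[out$report$module == "1"], "A1")
})
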