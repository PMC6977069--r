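test_that("extract_pair_subnetwork keeps exactly the inter-group edges", {
  net <- toy_network()
  sub <- extract_pair_subnetwork(net, "Bacillariophyta", "Copepoda")
  expect_equal(nrow(sub$edges), 3)
  expect_setequal(sub$annotations$barcode_id, c("d1", "d2", "c1", "c2"))
  # symmetric in (focal, partner)
  sub2 <- extract_pair_subnetwork(net, "Copepoda", "Bacillariophyta")
  expect_setequal(paste(sub$edges$node_a, sub$edges$node_b),
                  paste(sub2$edges$node_a, sub2$edges$node_b))
  # sign filter can empty the subnetwork
  sub3 <- extract_pair_subnetwork(net, "Bacillariophyta", "Dinophyceae",
                                  sign_filter = "copresence")
  expect_equal(nrow(sub3$edges), 0)
  expect_equal(nrow(sub3$annotations), 0)
  expect_error(extract_pair_subnetwork(net, "Bacillariophyta", "Nope"),
               "unknown group")
  expect_error(extract_pair_subnetwork(net, "Copepoda", "Copepoda"),
               "must differ")
})

test_that("metrics reproduce hand-computed values on canonical graphs", {
  star4 <- igraph::make_star(4, mode = "undirected")
  igraph::V(star4)$name <- letters[1:4]
  expect_equal(graph_density(star4), 0.5)
  expect_equal(degree_centralization(star4), 1)
  cycle5 <- igraph::make_ring(5)
  igraph::V(cycle5)$name <- letters[1:5]
  expect_equal(degree_centralization(cycle5), 0)
  path4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(degree_centralization(path4), 2 / 6)
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(graph_density(path3), 2 / 3)
  expect_equal(unname(node_betweenness(path3)[c("a", "b", "c")]),
               c(0, 1, 0))
  star5 <- igraph::make_star(5, mode = "undirected")
  igraph::V(star5)$name <- letters[1:5]
  expect_equal(max(node_betweenness(star5)), 1)
  expect_equal(count_components(igraph::make_graph(~ a - b, c - d)), 2)
  expect_equal(count_components(igraph::make_graph(~ a - b, b - c, d - e)),
               2)
  expect_equal(count_components(igraph::make_empty_graph(0,
                                                         directed = FALSE)),
               0)
  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:5]
  expect_equal(graph_density(edgeless), 0)
  expect_error(graph_density(igraph::make_empty_graph(1,
                                                      directed = FALSE)),
               "at least 2")
  expect_error(degree_centralization(igraph::make_graph(~ a - b)),
               "at least 3")
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:7, 1)
    g <- random_igraph(n, stats::runif(1, 0.2, 0.9))
    expect_equal(count_components(g), oracle_components(g))
    expect_equal(graph_diameter(g), oracle_diameter(g))
    expect_equal(graph_density(g), oracle_density(g))
    if (n >= 3) {
      expect_equal(degree_centralization(g), oracle_centralization(g))
      expect_equal(unname(node_betweenness(g)), oracle_betweenness(g),
                   tolerance = 1e-10)
    }
  }
})

test_that("density and centralization are invariant under relabeling", {
  set.seed(7)
  g <- random_igraph(7, 0.5)
  perm <- sample(7)
  h <- igraph::permute(g, perm)
  expect_equal(graph_density(g), graph_density(h))
  expect_equal(degree_centralization(g), degree_centralization(h))
})

test_that("adding an edge never increases the component count", {
  set.seed(13)
  for (i in 1:25) {
    g <- random_igraph(6, 0.3)
    # components are counted over non-isolated nodes, so the monotone
    # property is asserted on graphs without isolated nodes
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    n <- igraph::vcount(g)
    if (n < 2) next
    A <- oracle_adjacency(g)
    pairs <- utils::combn(n, 2)
    base <- count_components(g)
    for (j in seq_len(ncol(pairs))) {
      if (A[pairs[1, j], pairs[2, j]] == 0) {
        h <- igraph::add_edges(g, pairs[, j])
        expect_lte(count_components(h), base)
      }
    }
  }
})

test_that("exclusion_strength computes mean and sample sd", {
  ann <- make_annotations(c("a", "b", "c"), c("F", "P", "P"))
  ed <- make_edges(c("a", "a"), c("b", "c"), c(-0.5, -0.7))
  sub <- extract_pair_subnetwork(interaction_network(ann, ed), "F", "P")
  s <- exclusion_strength(sub)
  expect_equal(unname(s["mean"]), -0.6)
  expect_equal(unname(s["sd"]), sqrt(0.02), tolerance = 1e-12)
  # a single exclusion: sd 0 with a warning, not an error
  ed1 <- make_edges("a", "b", -0.66)
  sub1 <- extract_pair_subnetwork(interaction_network(ann, ed1), "F", "P")
  expect_warning(s1 <- exclusion_strength(sub1), "single exclusion")
  expect_equal(unname(s1), c(-0.66, 0))
  # no exclusions at all is an error
  edc <- make_edges("a", "b", 0.5)
  subc <- extract_pair_subnetwork(interaction_network(ann, edc), "F", "P")
  expect_error(exclusion_strength(subc), "no exclusion")
})

test_that("generated exclusion scores concentrate around the planted mean", {
  spec <- small_spec(n_edges = 500, p_ex = 1, seed = 21)
  net <- generate_network(spec)$network
  sub <- extract_pair_subnetwork(net, "A", "B")
  s <- exclusion_strength(sub)
  expect_lt(abs(s["mean"] - (-0.66)), 3 * 0.09 / sqrt(500))
})

test_that("compare_strengths implements the Welch test", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  r <- compare_strengths(x, y)
  expect_equal(r$t_statistic, -1.0954451, tolerance = 1e-6)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 0.3155, tolerance = 1e-3)
  # agrees with the reference implementation
  ref <- stats::t.test(x, y)
  expect_equal(r$t_statistic, unname(ref$statistic))
  expect_equal(r$df, unname(ref$parameter))
  expect_equal(r$p_value, ref$p.value)
  # identical samples: t = 0, p = 1
  r0 <- compare_strengths(x, x)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  # antisymmetry under swap
  r1 <- compare_strengths(y, x)
  expect_equal(r1$t_statistic, -r$t_statistic)
  expect_equal(r1$p_value, r$p_value)
  expect_error(compare_strengths(1, y), "at least 2")
  expect_error(compare_strengths(c(1, 1), c(1, 1)), "degenerate")
})

test_that("topology_report bundles consistent metrics", {
  # star: f1 connected to p1..p3
  ann <- make_annotations(c("f1", "p1", "p2", "p3"),
                          c("F", "P", "P", "P"))
  ed <- make_edges(rep("f1", 3), paste0("p", 1:3), c(0.5, 0.6, -0.7))
  sub <- extract_pair_subnetwork(interaction_network(ann, ed), "F", "P")
  rep <- topology_report(sub)
  expect_equal(rep$n_nodes, 4)
  expect_equal(rep$n_edges, 3)
  expect_equal(rep$density, 0.5)
  expect_equal(rep$centralization, 1)
  expect_equal(rep$diameter, 2)
  expect_equal(rep$avg_neighbors, 1.5)
  expect_equal(rep$n_components, 1)
  expect_equal(rep$n_components_copresence, 1)
  expect_equal(rep$n_components_exclusion, 1)
  expect_equal(rep$mean_exclusion_score, -0.7)
  expect_true(all(rep$betweenness >= 0 & rep$betweenness <= 1))
  expect_error(topology_report(
    extract_pair_subnetwork(interaction_network(ann), "F", "P")),
    "empty subnetwork")
})

test_that("topology_report is internally consistent on generated data", {
  spec <- small_spec(n_edges = 120, p_ex = 0.4, seed = 9)
  net <- generate_network(spec)$network
  sub <- extract_pair_subnetwork(net, "A", "B")
  rep <- topology_report(sub)
  expect_equal(rep$density,
               rep$n_edges / (rep$n_nodes * (rep$n_nodes - 1) / 2))
  expect_equal(rep$avg_neighbors, 2 * rep$n_edges / rep$n_nodes)
  expect_true(all(rep$betweenness >= 0 & rep$betweenness <= 1))
  expect_equal(length(rep$betweenness), rep$n_nodes)
  # sign-split component counts computed on the sign-filtered subgraphs
  co <- extract_pair_subnetwork(net, "A", "B", sign_filter = "copresence")
  expect_equal(rep$n_components_copresence, count_components(co))
})
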