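star14 <- tree_graph(template_edges("star", 14), 14)
line14 <- tree_graph(template_edges("line", 14), 14)

test_that("star closed forms: hub and leaf nodal values", {
  nd <- nodal_metrics(star14)
  expect_equal(nd$betweenness[1], 1)            # central node
  expect_true(all(nd$betweenness[-1] == 0))     # leaves
  expect_equal(nd$eccentricity[1], 1L)
  expect_true(all(nd$eccentricity[-1] == 2L))
  expect_equal(nd$degree[1], 13L)
  expect_equal(sum(nd$degree), 2L * 13L)        # handshake on N - 1 edges
})

test_that("star and line global closed forms", {
  gs <- global_metrics(star14)
  expect_equal(gs$leaf_fraction, 1)
  expect_equal(gs$tree_hierarchy, 0.5)
  expect_equal(gs$diameter, 2 / 13)
  expect_equal(gs$kappa, 7)               # (13^2 + 13) / 26
  expect_equal(gs$eccentricity, 1)        # range variant
  expect_equal(gs$k_max, 13L)

  gl <- global_metrics(line14)
  expect_equal(gl$leaf_fraction, 2 / 13)
  expect_equal(gl$diameter, 1)
  expect_equal(gl$kappa, 50 / 26)         # (2*1 + 12*4) / 26
  expect_equal(global_metrics(line14, ecc_variant = "max")$eccentricity, 13)

  expect_error(global_metrics(tree_graph(cbind(1, 2), 2)), "fewer than 3")
})

test_that("betweenness and eccentricity match brute-force path enumeration", {
  set.seed(7)
  for (i in 1:30) {
    tr <- random_tree(8)
    nd <- nodal_metrics(tr)
    expect_equal(nd$betweenness, oracle_bc(tr$adjacency), tolerance = 1e-12)
  }
})

test_that("betweenness and eccentricity agree with igraph", {
  set.seed(9)
  for (i in 1:10) {
    tr <- random_tree(12)
    nd <- nodal_metrics(tr)
    g <- igraph::graph_from_adjacency_matrix(tr$adjacency, mode = "undirected")
    bc_ig <- 2 * igraph::betweenness(g, directed = FALSE) / (11 * 10)
    expect_equal(nd$betweenness, unname(bc_ig), tolerance = 1e-10)
    expect_equal(nd$eccentricity, unname(igraph::eccentricity(g)))
  }
})

test_that("worked leaf-count and overlap arithmetic", {
  # a 14-node tree with 10 leaves: 10 spokes off node 1 plus a 3-node tail
  t10 <- tree_graph(rbind(cbind(1, 2:11), c(2, 12), c(12, 13), c(13, 14)), 14)
  expect_equal(sum(rowSums(t10$adjacency) == 1), 10L)
  expect_equal(round(global_metrics(t10)$leaf_fraction, 2), 0.77)

  # and one with 8 leaves: 8 spokes plus a 5-edge tail
  t8 <- tree_graph(rbind(cbind(1, 2:9), c(2, 10), c(10, 11), c(11, 12),
                         c(12, 13), c(13, 14)), 14)
  expect_equal(sum(rowSums(t8$adjacency) == 1), 8L)
  expect_equal(round(global_metrics(t8)$leaf_fraction, 2), 0.62)

  # two 14-node trees sharing exactly 3 edges
  shared <- rbind(c(1, 2), c(2, 3), c(3, 4))
  a <- tree_graph(rbind(shared, cbind(4, 5:14)), 14)
  b <- tree_graph(rbind(shared, cbind(1, 5:14)), 14)
  ov <- overlap(a, b)
  expect_equal(ov$shared_edges, 3L)
  expect_equal(round(ov$overlap_percent, 2), 23.08)

  expect_equal(overlap(a, a)$overlap_percent, 100)
  # star whose hub is a line endpoint: exactly the first line edge is shared
  star_1 <- tree_graph(template_edges("star", 14), 14)
  ov2 <- overlap(star_1, line14)
  expect_equal(ov2$shared_edges, 1L)
  expect_equal(ov2$overlap_fraction, 1 / 13)
  expect_error(overlap(star_1, tree_graph(cbind(1, 2:5), 5)), "different")
})

test_that("hub and edge occurrence fractions", {
  # 7 of 9 trees have node 1 as a hub -> 77.8%
  hub_tree <- tree_graph(rbind(c(1, 2), c(1, 3), c(3, 4)), 4)
  leaf_tree <- tree_graph(rbind(c(2, 1), c(2, 3), c(3, 4)), 4)
  occ <- occurrence(c(replicate(7, hub_tree, simplify = FALSE),
                      replicate(2, leaf_tree, simplify = FALSE)))
  expect_equal(round(100 * occ$hubs$occurrence[1], 1), 77.8)

  # identical trees: every tree edge at 100%, nothing else reported
  occ1 <- occurrence(replicate(5, hub_tree, simplify = FALSE))
  expect_true(all(occ1$edges$occurrence == 1))
  expect_equal(nrow(occ1$edges), 3L)

  # counting oracle: occurrences sum to total counts / n
  set.seed(15)
  trees <- replicate(9, random_tree(6), simplify = FALSE)
  occ2 <- occurrence(trees)
  total_edges <- sum(vapply(trees, function(t) nrow(t$edges), numeric(1)))
  expect_equal(sum(occ2$edges$occurrence) * 9, total_edges)
  total_hubs <- sum(vapply(trees, function(t)
    sum(rowSums(t$adjacency) > 1), numeric(1)))
  expect_equal(sum(occ2$hubs$occurrence) * 9, total_hubs)
  expect_true(all(occ2$edges$occurrence >= 0 & occ2$edges$occurrence <= 1))
})

test_that("structural identities and relabeling invariance", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:14, 1)
    tr <- random_tree(n)
    g <- global_metrics(tr)
    # leaf fraction times N-1 is the integer leaf count
    expect_equal(g$leaf_fraction * (n - 1), round(g$leaf_fraction * (n - 1)))
    expect_true(g$leaf_fraction >= 2 / (n - 1) && g$leaf_fraction <= 1)
    expect_true(g$tree_hierarchy >= 0 && g$tree_hierarchy <= 1)
    expect_true(g$kappa >= 2 - 2 / n)
    # a star always scores T_H = 0.5 (the converse fails for some trees,
    # e.g. the 4-node line); D = 1 exactly characterizes a line
    is_star <- g$k_max == n - 1
    if (is_star) expect_equal(g$tree_hierarchy, 0.5)
    is_line <- all(rowSums(tr$adjacency) <= 2)
    expect_equal(g$diameter == 1, is_line)

    perm <- sample(n)
    # relabel: map each edge through perm
    tr2 <- tree_graph(cbind(perm[tr$edges[, 1]], perm[tr$edges[, 2]]), n)
    g2 <- global_metrics(tr2)
    expect_equal(as.data.frame(g2), as.data.frame(g))
  }
})
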