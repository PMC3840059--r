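test_that("binarization keeps exactly the strictly supra-threshold edges", {
  W <- matrix(c(0, 2, 0, 2, 0, 0, 0, 0, 0), 3)
  expect_equal(binarize(weighted_network(W), 0)$A[1, 2], 1)
  expect_equal(sum(binarize(weighted_network(W), 0)$A), 2)
  expect_equal(sum(binarize(weighted_network(W), 2)$A), 0)   # tau at max weight

  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 1; W2[2, 3] <- W2[3, 2] <- 3
  b <- binarize(weighted_network(W2), 1)                      # strict >: drops the weight-1 edge
  expect_equal(b$A[2, 3], 1)
  expect_equal(sum(b$A), 2)

  expect_error(binarize(weighted_network(W2), -1), "nonnegative")
})

test_that("network constructors reject malformed matrices", {
  expect_error(weighted_network(matrix(1:6, 2)), "square")
  M <- matrix(c(0, 1, 2, 0), 2)
  expect_error(weighted_network(M), "symmetric")
  M2 <- matrix(c(1, 0, 0, 0), 2)
  expect_error(weighted_network(M2), "diagonal")
  expect_error(binary_network(matrix(c(0, 2, 2, 0), 2)), "0 or 1")
})

test_that("degrees and degree survival follow their definitions", {
  expect_equal(unname(node_degrees(k3())), c(2, 2, 2))
  expect_equal(unname(node_degrees(star5())), c(4, 1, 1, 1, 1))
  expect_equal(unname(node_degrees(edgeless(4))), rep(0L, 4))
  expect_equal(mean(node_degrees(k3())), 2 * 3 / 3)  # 2 * edges / n

  expect_equal(degree_survival(k3(), 1), 1.0)
  expect_equal(degree_survival(k3(), 2), 0.0)
  expect_equal(degree_survival(star5(), 1), 0.2)     # only the hub exceeds 1

  d0 <- 0:6
  s <- degree_survival(random_binary_net(20, 0.3, seed = 3), d0)
  expect_true(all(diff(s) <= 0))
  net <- random_binary_net(15, 0.4, seed = 4)
  d <- node_degrees(net)
  expect_equal(degree_survival(net, min(d) - 1), 1)
  expect_equal(degree_survival(net, max(d)), 0)
})

test_that("clustering matches hand counts and lies in [0, 1]", {
  expect_equal(clustering_coefficient(k3())$mean, 1)
  expect_equal(clustering_coefficient(path3())$mean, 0)
  ## K4 minus one edge: two nodes see all neighbor pairs connected, two see 2 of 3
  expect_equal(clustering_coefficient(k4_minus_edge())$mean, (1 + 1 + 2 / 3 + 2 / 3) / 4)
  ## degree < 2 contributes 0, not NA
  expect_equal(clustering_coefficient(star5())$per_node[["v2"]], 0)
  cn <- clustering_coefficient(random_binary_net(25, 0.25, seed = 5))$per_node
  expect_true(all(cn >= 0 & cn <= 1))
})

test_that("mean geodesic averages unordered pairs on the giant component", {
  expect_equal(mean_geodesic(k3()), 1)
  expect_equal(mean_geodesic(path3()), 4 / 3)       # distances 1, 1, 2
  expect_equal(mean_geodesic(two_triangles()), 1)   # computed on one triangle
  expect_error(mean_geodesic(edgeless(5)), "undefined")
})

test_that("transitivity equals 3t/q with distinct triangle and two-path counts", {
  expect_equal(graph_transitivity(k3()), 1)      # t = 1, q = 3
  expect_equal(graph_transitivity(star5()), 0)
  expect_equal(graph_transitivity(k4()), 1)      # t = 4, q = 12
  expect_error(graph_transitivity(edgeless(3)), "undefined")
  tr <- graph_transitivity(random_binary_net(20, 0.3, seed = 6))
  expect_true(tr >= 0 && tr <= 1)
})

test_that("transitivity and clustering of dense random graphs approach the edge density", {
  ## for G(n, p) both statistics concentrate near p
  net <- random_binary_net(300, 0.2, seed = 11)
  expect_equal(graph_transitivity(net), 0.2, tolerance = 0.05)
  expect_equal(clustering_coefficient(net)$mean, 0.2, tolerance = 0.05)
})

test_that("giant component takes the largest component, ties to smallest index", {
  expect_equal(giant_component(k3())$size, 3)
  expect_equal(giant_component(edgeless(7))$size, 1)
  tt <- net_from_edges(7, list(c(2, 3), c(3, 4), c(2, 4), c(5, 6), c(6, 7), c(5, 7)))
  gc <- giant_component(tt)   # two triangles + isolated node 1; tie -> contains node 2
  expect_equal(gc$size, 3)
  expect_equal(gc$nodes, c(2L, 3L, 4L))
})

test_that("metrics after binarize(., 0) are invariant to positive rescaling of weights", {
  set.seed(8)
  W <- matrix(0, 10, 10)
  W[upper.tri(W)] <- stats::runif(45) * (stats::runif(45) < 0.5)
  W <- W + t(W)
  m1 <- network_metrics(binarize(weighted_network(W), 0))
  m2 <- network_metrics(binarize(weighted_network(W * 37.5), 0))
  expect_equal(m1, m2)
})

test_that("metrics_table reports one row per network with degenerate values as NA", {
  tab <- metrics_table(list(a = k3(), b = edgeless(3)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$id, c("a", "b"))
  expect_true(is.na(tab$transitivity[2]))
  expect_true(is.na(tab$mean_geodesic[2]))
  expect_equal(tab$mean_degree[1], 2)
})
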