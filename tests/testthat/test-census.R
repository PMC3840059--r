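test_that("canonical keys identify graphs up to isomorphism", {
  p_a <- rbind(c(1, 2), c(2, 3))
  p_b <- rbind(c(3, 1), c(1, 2))           # same 3-path, different labels
  expect_identical(canonical_key(p_a), canonical_key(p_b))

  c4 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  p4 <- rbind(c(1, 2), c(2, 3), c(3, 4))
  expect_false(canonical_key(c4) == canonical_key(p4))

  paw1 <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4))
  paw2 <- rbind(c(4, 2), c(2, 1), c(4, 1), c(4, 3))   # relabeled paw
  expect_identical(canonical_key(paw1), canonical_key(paw2))

  expect_error(canonical_key(igraph::make_ring(13)), "too large")
})

test_that("catalog sizes match exhaustive enumeration for short walks", {
  expect_equal(nrow(build_catalog(1)$classes), 1)   # a single edge
  expect_equal(nrow(build_catalog(2)$classes), 2)   # edge, 2-path
  ## length 3: edge, 2-path, 3-path, triangle
  cat3 <- build_catalog(3)
  expect_equal(nrow(cat3$classes), 4)
  expect_setequal(cat3$classes$key,
                  c(canonical_key(rbind(c(1, 2))),
                    canonical_key(rbind(c(1, 2), c(2, 3))),
                    canonical_key(rbind(c(1, 2), c(2, 3), c(3, 4))),
                    canonical_key(rbind(c(1, 2), c(2, 3), c(1, 3)))))
  expect_error(build_catalog(0), "positive")
})

test_that("catalogs are nested in walk length (every shorter-walk class persists)", {
  cats <- lapply(1:8, build_catalog)
  for (L in 2:8) {
    expect_true(all(cats[[L - 1]]$classes$key %in% cats[[L]]$classes$key),
                info = paste("L =", L))
  }
})

test_that("covering walk counts match direct listings", {
  e1 <- rbind(c(1, 2))
  expect_equal(covering_walk_count(e1, 1), 2)   # one walk per direction
  expect_equal(covering_walk_count(e1, 8), 2)   # forced alternation
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  expect_equal(covering_walk_count(tri, 3), 6)  # 3 starts x 2 directions
  ## 2-path at L = 2: b-a-c and c-a-b... all walks covering both edges
  p2 <- rbind(c(1, 2), c(2, 3))
  expect_equal(covering_walk_count(p2, 2), 2)
  expect_equal(covering_walk_count(tri, 2), 0)  # more edges than steps
})

test_that("subgraph instance counts match combinatorial values", {
  expect_equal(count_subgraph_instances(k3(), rbind(c(1, 2))), 3)
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  expect_equal(count_subgraph_instances(k4(), tri), 4)
  p2 <- rbind(c(1, 2), c(2, 3))
  expect_equal(count_subgraph_instances(star5(), p2), 6)    # C(4, 2)
  expect_equal(count_subgraph_instances(star5(), tri), 0)
})

test_that("triangle census at walk length 2 reproduces the exhaustive walk listing", {
  cat2 <- build_catalog(2)
  cc <- census_walk_counts(k3(), cat2, method = "direct")
  expect_equal(sum(cc), 12)                     # 3 starts x 2 steps x 2 choices
  expect_equal(unname(cc[canonical_key(rbind(c(1, 2)))]), 6)
  expect_equal(unname(cc[canonical_key(rbind(c(1, 2), c(2, 3)))]), 6)
})

test_that("single-edge and edgeless networks give degenerate censuses", {
  cat8 <- build_catalog(8)
  cc <- census_walk_counts(single_edge(), cat8)
  expect_equal(unname(cc[canonical_key(rbind(c(1, 2)))]), 2)
  expect_equal(sum(cc), 2)
  expect_equal(sum(census_walk_counts(edgeless(6), cat8)), 0)
})

test_that("direct and factorized censuses agree exactly on random graphs", {
  cats <- lapply(3:5, build_catalog)
  for (i in 1:12) {
    net <- random_binary_net(sample(6:12, 1), 0.3, seed = 100 + i)
    cg <- cats[[(i %% 3) + 1]]
    d <- census_walk_counts(net, cg, method = "direct")
    f <- census_walk_counts(net, cg, method = "factorized")
    expect_identical(d, f)
    if (sum(net$A) > 0)
      expect_equal(sum(f), total_walk_count(net, cg$walk_length))
  }
})

test_that("census of a disjoint union is the sum of the parts", {
  cat4 <- build_catalog(4)
  a <- random_binary_net(7, 0.4, seed = 21)
  b <- random_binary_net(6, 0.4, seed = 22)
  AB <- matrix(0, 13, 13)
  AB[1:7, 1:7] <- a$A
  AB[8:13, 8:13] <- b$A
  expect_equal(census_walk_counts(binary_network(AB), cat4),
               census_walk_counts(a, cat4) + census_walk_counts(b, cat4))
})

test_that("isomorphic networks have identical embeddings", {
  cat4 <- build_catalog(4)
  net <- random_binary_net(9, 0.35, seed = 31)
  perm <- sample(9)
  net2 <- binary_network(net$A[perm, perm])
  expect_equal(unname(census_walk_counts(net, cat4)),
               unname(census_walk_counts(net2, cat4)))
})

test_that("cohort embedding has catalog columns and deterministic rows", {
  cat3 <- build_catalog(3)
  nets <- list(x = k3(), y = k3(), z = edgeless(3))
  X <- embed_cohort(nets, cat3)
  expect_equal(dim(X), c(3, 4))
  expect_equal(X[1, ], X[2, ])        # identical networks, identical rows
  expect_equal(unname(X[3, ]), rep(0, 4))
  expect_equal(colnames(X), cat3$classes$key)
  expect_error(embed_cohort(list(), cat3), "at least one")
})

test_that("catalog JSON round-trips", {
  cat4 <- build_catalog(4)
  tmp <- tempfile(fileext = ".json")
  write_catalog(cat4, tmp)
  back <- read_catalog(tmp)
  expect_equal(back$walk_length, 4L)
  expect_equal(back$classes, cat4$classes)
  net <- random_binary_net(8, 0.4, seed = 41)
  expect_equal(census_walk_counts(net, back), census_walk_counts(net, cat4))
})
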