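test_that("degree centrality divides by n - 1", {
  star <- toy_net(rep(1, 5), 11:15)
  dc <- degree_centrality(star, "total")
  expect_equal(dc$value[dc$id == "n001"], 1.0)
  net <- toy_net(c(1, 1, 2), c(11, 12, 11))
  dc <- degree_centrality(net, "total")
  deg <- node_degrees(net)
  expect_equal(dc$value[match(deg$id, dc$id)], deg$k_total / 3)
  expect_true(all(dc$value >= 0 & dc$value <= 1))
})

test_that("BFS distances match Floyd-Warshall and directed reachability", {
  path <- toy_net(c(1, 2), c(2, 3))
  D <- all_pairs_distances(path, "undirected")
  expect_equal(D["n001", "n003"], 2L)
  # directed: a target cannot reach back
  de <- toy_net(1, 11)
  Dd <- all_pairs_distances(de, "directed_out")
  expect_true(is.na(Dd["n011", "n001"]))
  expect_equal(Dd["n001", "n011"], 1L)
  set.seed(5)
  for (sense in c("undirected", "directed_out", "directed_in")) {
    e <- random_edges(15, p = 0.15)
    net <- toy_net(e$from, e$to)
    D <- all_pairs_distances(net, sense)
    FW <- floyd_warshall(dense_adjacency(net, sense))
    FW[is.infinite(FW)] <- NA
    expect_equal(unclass(D), matrix(as.integer(FW), nrow(FW),
                                    dimnames = dimnames(D)),
                 ignore_attr = TRUE)
  }
})

test_that("closeness follows the component-scaled convention", {
  star <- toy_net(rep(1, 5), 11:15)
  cc <- closeness_centrality(star, "undirected")
  expect_equal(cc$value[cc$id == "n001"], 1.0)
  # disconnected fixture vs direct-sum oracle applying the same formula
  e <- rbind(random_edges(6, p = 0.4),
             data.frame(from = 7:8, to = 9:10))
  net <- toy_net(e$from, e$to)
  for (sense in c("undirected", "directed_in")) {
    cc <- closeness_centrality(net, sense)
    # oracle distances: d(u, v) along forward drug->target edges for the
    # incoming sense, symmetric distances for the undirected sense
    FW <- floyd_warshall(dense_adjacency(
      net, if (sense == "directed_in") "directed_out" else "undirected"
    ))
    n <- nrow(FW)
    for (v in seq_len(n)) {
      d <- FW[, v]
      d <- d[-v]
      d <- d[is.finite(d) & d > 0]
      want <- if (length(d) == 0) 0 else
        (length(d) / sum(d)) * (length(d) / (n - 1))
      expect_equal(cc$value[cc$id == net$nodes$id[v]], want)
    }
  }
})

test_that("betweenness equals explicit shortest-path enumeration", {
  # path a-b-c: the middle vertex carries every pair
  p3 <- toy_net(c(1, 2), c(2, 3))
  bc <- betweenness_centrality(p3, "undirected")
  expect_equal(bc$value[bc$id == "n002"], 1.0)
  expect_equal(sum(bc$value), 1.0)
  set.seed(9)
  for (trial in 1:12) {
    n <- sample(5:9, 1)
    e <- random_edges(n, p = 0.3)
    if (nrow(e) < 2) next
    net <- toy_net(e$from, e$to)
    for (sense in c("directed_out", "undirected")) {
      bc <- betweenness_centrality(net, sense)
      want <- brute_betweenness(dense_adjacency(net, sense))
      expect_equal(bc$value[match(net$nodes$id, bc$id)], want,
                   tolerance = 1e-12)
    }
  }
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  tri <- toy_net(c(1, 2, 3), c(2, 3, 1))
  ec <- eigenvector_centrality(tri)
  expect_equal(ec$value, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  set.seed(13)
  e <- random_edges(12, p = 0.3)
  net <- toy_net(e$from, e$to)
  comp <- weak_components(net)
  ec <- eigenvector_centrality(net, component = 1)
  keep <- which(comp$component_of == 1)
  A <- dense_adjacency(net, "undirected")[keep, keep]
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1]
  v <- abs(v) / sqrt(sum(v^2)) # PF vector is sign-free; ours is positive
  got <- ec$value[match(net$nodes$id[keep], ec$id)]
  expect_lt(max(abs(got - v)), 1e-8)
  # fixed point: ||Ax - lambda x||_inf below tolerance
  lam <- attr(ec, "lambda")
  expect_lt(max(abs(A %*% got - lam * got)), 1e-6)
  # nodes outside the component score zero
  outside <- ec$value[match(net$nodes$id[-keep], ec$id)]
  if (length(outside)) expect_true(all(outside == 0))
})

test_that("rankings are deterministic with lexicographic tie-break", {
  net <- toy_net(c(1, 2, 3), c(11, 12, 13))
  sc <- degree_centrality(net, "out")
  top <- top_nodes(sc, 3)
  # drugs all tie at 1 edge: lexicographic order among equal values
  expect_equal(top$id, c("n001", "n002", "n003"))
  expect_warning(full <- top_nodes(sc, 100), "truncating")
  expect_setequal(full$id, net$nodes$id)
  expect_true(all(diff(full$value) <= 0))
})
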