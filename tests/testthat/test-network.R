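test_that("dual-role merging unifies same-named drugs and targets", {
  tab <- interaction_table(tibble::tibble(
    drug_id = c("D1", "D1", "t1 "),
    drug_name = c("D1", "D1", "t1 "),
    target_id = c("T1", "T2", "T3"),
    target_name = c("T1", "T2", "T3")
  ))
  net <- build_network(tab)
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 3L)
  merged <- net$nodes[net$nodes$id == "t1", ]
  expect_equal(merged$role, "both")
  # without merging, namespaces stay disjoint
  net2 <- build_network(tab, merge_dual_roles = FALSE)
  expect_equal(nrow(net2$nodes), 5L)
  expect_true(all(net2$nodes$role != "both"))
})

test_that("disjoint name universes give strictly disjoint roles", {
  tab <- interaction_table(tibble::tibble(
    drug_id = sprintf("D%d", 1:4),
    target_id = sprintf("T%d", c(1, 1, 2, 3))
  ))
  net <- build_network(tab)
  expect_equal(nrow(net$nodes), 4 + 3)
  rep <- check_bipartite(net)
  expect_true(rep$role_disjoint)
  expect_true(rep$two_colorable)
  expect_null(rep$witness_odd_cycle)
})

test_that("a merged triangle is caught with an odd-cycle witness", {
  tab <- interaction_table(tibble::tibble(
    drug_id = c("A", "B", "C"),
    target_id = c("B", "C", "A")
  ))
  net <- build_network(tab)
  rep <- check_bipartite(net)
  expect_false(rep$role_disjoint)
  expect_false(rep$two_colorable)
  w <- rep$witness_odd_cycle
  expect_equal(w[1], w[length(w)]) # closed
  expect_equal(length(w) %% 2, 0) # odd cycle: odd #edges = even list with repeat
})

test_that("two-colorability agrees with brute-force enumeration", {
  set.seed(101)
  for (trial in 1:40) {
    n <- sample(3:10, 1)
    e <- random_edges(n, p = 0.18)
    if (nrow(e) == 0) next
    net <- toy_net(e$from, e$to)
    rep <- check_bipartite(net)
    # oracle: try all 2^n colorings of the undirected view
    A <- dense_adjacency(net, "undirected")
    m <- nrow(A)
    ok <- FALSE
    for (mask in 0:(2^m - 1)) {
      col <- as.integer(intToBits(mask))[seq_len(m)]
      conflict <- A * outer(col, col, "==")
      if (sum(conflict) == 0) { ok <- TRUE; break }
    }
    expect_equal(rep$two_colorable, ok)
    if (!rep$two_colorable) {
      # witness is a genuine odd closed walk in the graph
      w <- match(rep$witness_odd_cycle, net$nodes$id)
      steps <- cbind(w[-length(w)], w[-1])
      expect_true(all(A[steps] > 0))
      expect_equal((length(w) - 1) %% 2, 1)
    }
  }
})

test_that("weak components partition the graph with deterministic indexing", {
  # two components: sizes 4 (giant) and 2, plus an isolated pair
  tab <- interaction_table(tibble::tibble(
    drug_id = c("D1", "D1", "D2", "E1"),
    target_id = c("T1", "T2", "T2", "U1")
  ))
  net <- build_network(tab)
  comp <- weak_components(net)
  expect_equal(comp$sizes, c(4L, 2L))
  expect_equal(comp$giant_index, 1L)
  expect_equal(sum(comp$sizes), nrow(net$nodes))
  expect_equal(comp$size_histogram$n_components[comp$size_histogram$size == 2],
               1L)
})

test_that("extracted components conserve nodes and edges", {
  set.seed(7)
  e <- random_edges(12, p = 0.12)
  net <- toy_net(e$from, e$to)
  comp <- weak_components(net)
  parts <- lapply(seq_along(comp$sizes), function(i)
    extract_component(net, i, comp))
  expect_equal(sum(vapply(parts, function(p) nrow(p$nodes), integer(1))),
               nrow(net$nodes))
  expect_equal(sum(vapply(parts, function(p) nrow(p$edges), integer(1))),
               nrow(net$edges))
  # each size-2 component is a single edge
  for (i in which(comp$sizes == 2)) {
    expect_equal(nrow(parts[[i]]$edges), 1L)
  }
  expect_error(extract_component(net, length(comp$sizes) + 1L),
               "out of range")
  # extracting the giant of a connected graph returns the graph itself
  con <- toy_net(c(1, 2, 3), c(2, 3, 4))
  expect_equal(nrow(extract_component(con, 1)$nodes), nrow(con$nodes))
})

test_that("role disjointness implies two-colorability for unmerged graphs", {
  set.seed(31)
  for (trial in 1:10) {
    e <- random_edges(8, p = 0.3)
    if (nrow(e) == 0) next
    net <- toy_net(e$from, e$to, merge = FALSE)
    rep <- check_bipartite(net)
    expect_true(rep$role_disjoint)
    expect_true(rep$two_colorable)
  }
})
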