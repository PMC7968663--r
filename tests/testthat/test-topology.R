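test_that("degrees match hand enumeration and satisfy the handshake lemma", {
  # D1 -> {T1, T2}, D2 -> {T1}, T1 -> T2 (dual-role T1)
  net <- toy_net(c(1, 1, 2, 11), c(11, 12, 11, 12))
  deg <- node_degrees(net)
  expect_equal(deg$k_out[deg$id == "n001"], 2L)
  expect_equal(deg$k_in[deg$id == "n011"], 2L)
  expect_equal(deg$k_out[deg$id == "n011"], 1L)
  expect_equal(deg$k_in[deg$id == "n012"], 2L)
  expect_equal(deg$k_total, deg$k_in + deg$k_out)
  set.seed(11)
  for (trial in 1:10) {
    e <- random_edges(sample(4:12, 1), p = 0.3)
    if (nrow(e) == 0) next
    net <- toy_net(e$from, e$to)
    deg <- node_degrees(net)
    expect_equal(sum(deg$k_in), nrow(net$edges))
    expect_equal(sum(deg$k_out), nrow(net$edges))
  }
})

test_that("mean degree follows the 2E/V convention", {
  expect_equal(mean_degree(toy_net(1, 2)), 1.0)
  # complete bipartite 3x3: 2*9/6
  e <- expand.grid(from = 1:3, to = 11:13)
  expect_equal(mean_degree(toy_net(e$from, e$to)), 3.0)
})

test_that("empirical distribution counts degree-positive nodes", {
  deg <- tibble::tibble(
    id = letters[1:4], role = "drug",
    k_in = 0L, k_out = c(0L, 1L, 1L, 2L), k_total = c(0L, 1L, 1L, 2L)
  )
  d <- degree_distribution(deg, "out")
  expect_equal(d$k, c(1L, 2L))
  expect_equal(d$p, c(2 / 3, 1 / 3))
  expect_equal(attr(d, "n_zero"), 1L)
  expect_error(degree_distribution(
    tibble::tibble(id = "a", role = "drug", k_in = 0L, k_out = 0L,
                   k_total = 0L), "out"), "zero")
  # regular graph: single support point with probability 1
  ring <- toy_net(1:4, c(2, 3, 4, 1))
  dr <- degree_distribution(node_degrees(ring), "total")
  expect_equal(dr$k, 2L)
  expect_equal(dr$p, 1)
})

test_that("least squares recovers an exact power law to machine precision", {
  k <- 1:100
  gamma <- 2.0
  p <- k^(-gamma) / sum(k^(-gamma))
  d <- new_degree_distribution(k, p)
  fit <- fit_power_law(d, method = "loglog_ls")
  expect_equal(fit$gamma, gamma, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # A reproduces the distribution at k_min
  expect_equal(fit$A * 1^(-fit$gamma), p[1], tolerance = 1e-9)
  expect_error(fit_power_law(new_degree_distribution(1:2, c(.6, .4))),
               "at least 3")
})

test_that("discrete MLE is consistent for heavy-tailed samples", {
  # inverse-CDF sampling from the unbounded discrete law via a far cutoff
  sample_discrete_pl <- function(n, gamma, cutoff = 1e6) {
    p <- (1:cutoff)^(-gamma)
    cdf <- cumsum(p / sum(p))
    findInterval(stats::runif(n), cdf) + 1L
  }
  set.seed(42)
  x <- sample_discrete_pl(1e5, 1.8)
  tab <- table(x)
  d <- new_degree_distribution(as.integer(names(tab)),
                               as.numeric(tab) / length(x))
  fit <- fit_power_law(d, method = "mle", samples = x)
  expect_lt(abs(fit$gamma - 1.8), 0.05)
  # estimator bias stays small across exponents (single seed per gamma)
  for (g in c(1.5, 2.0, 2.5)) {
    set.seed(round(g * 100))
    x <- sample_discrete_pl(1e5, g)
    fit <- fit_power_law(
      new_degree_distribution(
        as.integer(names(table(x))),
        as.numeric(table(x)) / length(x)
      ),
      method = "mle", samples = x
    )
    expect_lt(abs(fit$gamma - g), 0.05)
  }
})

test_that("clustering matches its definition on canonical graphs", {
  # triangle: every node closes its neighbour pair
  tri <- toy_net(c(1, 2, 3), c(2, 3, 1))
  expect_equal(clustering_profile(tri)$per_node$c, rep(1, 3))
  # strictly bipartite graphs have no triangles
  e <- expand.grid(from = 1:4, to = 11:14)
  bip <- toy_net(e$from, e$to)
  cp <- clustering_profile(bip)
  expect_equal(cp$mean_c, 0)
  expect_true(all(cp$per_node$c == 0))
})

test_that("clustering agrees with the cubic-time oracle on random graphs", {
  set.seed(77)
  for (trial in 1:5) {
    e <- random_edges(20, p = 0.12)
    net <- toy_net(e$from, e$to)
    cp <- clustering_profile(net)
    A <- dense_adjacency(net, "undirected")
    n <- nrow(A)
    for (v in seq_len(n)) {
      nb <- which(A[v, ] > 0)
      ki <- length(nb)
      ei <- if (ki < 2) 0 else sum(A[nb, nb]) / 2
      ci <- if (ki < 2) 0 else 2 * ei / (ki * (ki - 1))
      expect_equal(cp$per_node$c[v], ci)
      expect_equal(cp$per_node$e_among_neighbors[v], ei)
      expect_lte(ei, ki * (ki - 1) / 2)
    }
  }
})
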