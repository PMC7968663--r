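test_that("generation is byte-identical under a fixed seed", {
  p <- synthetic_params(n_drugs = 200, n_targets = 250, seed = 99)
  t1 <- generate_interactions(p)
  t2 <- generate_interactions(p)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_edge_table(t1, f1)
  write_edge_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- generate_interactions(synthetic_params(n_drugs = 200, n_targets = 250,
                                               seed = 100))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("structural knobs show up in the generated network", {
  # no dual roles: strictly role-disjoint
  p0 <- synthetic_params(n_dual_role = 0, seed = 5)
  net0 <- build_network(generate_interactions(p0))
  expect_true(check_bipartite(net0)$role_disjoint)
  # dual roles appear when requested
  p5 <- synthetic_params(n_dual_role = 5, seed = 5)
  net5 <- build_network(generate_interactions(p5))
  expect_equal(sum(net5$nodes$role == "both"), 5L)
  # isolated pairs become size-2 components beyond the core
  p <- synthetic_params(n_drugs = 1, n_targets = 1, k_max = 1,
                        n_dual_role = 0, n_isolated_pairs = 5, seed = 3)
  comp <- weak_components(build_network(generate_interactions(p)))
  expect_gte(length(comp$sizes), 6L)
  expect_gte(sum(comp$sizes == 2), 5L)
})

test_that("the out-degree law survives generation", {
  # recovery configuration: the in-side oversupplies stubs so balancing
  # never trims the out-degrees under study
  gammas <- vapply(1:5, function(s) {
    tab <- generate_interactions(synthetic_params(
      n_drugs = 3000, n_targets = 5000, gamma_out = 1.5, gamma_in = 1.2,
      k_max = 100, n_dual_role = 0, n_isolated_pairs = 0, seed = s
    ))
    deg <- node_degrees(build_network(tab))
    fit_power_law(degree_distribution(deg, "out", role_restrict = "drug"))$gamma
  }, numeric(1))
  expect_lt(abs(mean(gammas) - 1.5), 0.15)
  # chi-square goodness of the realized out-degrees against the target law
  pvals <- vapply(1:10, function(s) {
    tab <- generate_interactions(synthetic_params(
      n_drugs = 5000, n_targets = 9000, gamma_out = 1.6, gamma_in = 1.15,
      k_max = 60, n_dual_role = 0, n_isolated_pairs = 0, seed = 100 + s
    ))
    deg <- node_degrees(build_network(tab))
    k <- deg$k_out[deg$role == "drug" & deg$k_out > 0]
    law <- (1:60)^(-1.6)
    law <- law / sum(law)
    obs <- tabulate(pmin(k, 60L), nbins = 60)
    # pool the sparse tail so every expected count stays above 5
    expctd <- law * length(k)
    K <- max(which(expctd >= 5))
    pool <- function(x) c(x[seq_len(K)], sum(x[-seq_len(K)]))
    suppressWarnings(stats::chisq.test(pool(obs), p = pool(expctd) /
                                         sum(expctd))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("the landscape preset hits the published scale", {
  for (s in c(1, 2)) {
    tab <- generate_interactions(landscape_preset(seed = s))
    net <- build_network(tab)
    g <- glance(net)
    expect_lt(abs(g$n_edges - 9300) / 9300, 0.10)
    expect_lt(abs(g$n_drugs - 2200) / 2200, 0.10)
    expect_lt(abs(g$n_targets - 2700) / 2700, 0.10)
    expect_equal(g$n_dual_role, 13L)
    expect_gte(g$giant_frac, 0.80)
    comp <- weak_components(net)
    expect_gte(sum(comp$sizes == 2), 94)
  }
})

test_that("degenerate parameter requests are rejected", {
  expect_error(synthetic_params(gamma_out = 0.9), "gamma_out")
  expect_error(synthetic_params(n_dual_role = 50, n_drugs = 10,
                                n_targets = 10))
})
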