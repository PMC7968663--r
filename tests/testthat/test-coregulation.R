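test_that("projection counts shared targets per drug pair", {
  net <- build_network(chain_fixture())
  proj <- drug_projection(net)
  expect_equal(nrow(proj$edges), 2L)
  expect_equal(proj$edges$drug_a, c("d1", "d2"))
  expect_equal(proj$edges$drug_b, c("d2", "d3"))
  expect_equal(proj$edges$shared_targets, c(1L, 1L))
  pc <- proj$partner_count
  expect_equal(pc$n_partners[pc$id == "d2"], 2L)
  # one drug with many targets projects to nothing
  lone <- toy_net(rep(1, 5), 11:15)
  expect_equal(nrow(drug_projection(lone)$edges), 0L)
})

test_that("projection equals brute-force target-set intersections", {
  set.seed(19)
  for (trial in 1:6) {
    nd <- sample(4:8, 1)
    e <- data.frame(from = sample(nd, 25, TRUE),
                    to = 100 + sample(10, 25, TRUE))
    net <- toy_net(e$from, e$to)
    proj <- drug_projection(net)
    drug_ids <- net$nodes$id[net$nodes$is_drug]
    tsets <- lapply(drug_ids, function(d) {
      i <- match(d, net$nodes$id)
      net$nodes$id[net$out_adj[[i]]]
    })
    names(tsets) <- drug_ids
    for (i in seq_along(drug_ids)) {
      for (j in seq_along(drug_ids)) {
        if (i >= j) next
        shared <- length(intersect(tsets[[i]], tsets[[j]]))
        row <- proj$edges[proj$edges$drug_a == drug_ids[i] &
                            proj$edges$drug_b == drug_ids[j], ]
        expect_equal(nrow(row), as.integer(shared > 0))
        if (shared > 0) expect_equal(row$shared_targets, shared)
      }
    }
  }
})

test_that("coregulation ranking breaks ties lexicographically", {
  # all drugs share one common target: identical counts, ordered by id
  net <- toy_net(1:4, rep(11, 4))
  top <- top_coregulated(drug_projection(net), 4)
  expect_equal(top$id, c("n001", "n002", "n003", "n004"))
  expect_equal(top$n_partners, rep(3L, 4))
})

test_that("coverage verifies subsets faithfully", {
  net <- build_network(chain_fixture())
  full <- coverage(net, c("d1", "d2", "d3"))
  expect_true(full$covered)
  none <- coverage(net, character(0))
  expect_false(none$covered)
  expect_setequal(none$uncovered_targets, c("t1", "t2"))
  expect_error(coverage(net, "nope"), "unknown node")
})

test_that("a perfect matching admits no removals", {
  net <- toy_net(1:5, 11:15)
  res <- suppressWarnings( # 5 disjoint pairs: the multi-component warning fires
    dominating_set_reduction(net, iterations = 500, seed = 2)
  )
  expect_equal(length(res$retained), 5L)
  expect_equal(length(res$removed), 0L)
  expect_true(res$coverage_check)
})

test_that("the reduction is covering, minimal, and no smaller than optimal", {
  set.seed(41)
  for (trial in 1:6) {
    nd <- sample(5:9, 1)
    e <- data.frame(from = sample(nd, 30, TRUE),
                    to = 100 + sample(8, 30, TRUE))
    net <- toy_net(e$from, e$to)
    opt <- exact_min_cover_size(net)
    for (seed in c(1, 7)) {
      res <- suppressWarnings(
        dominating_set_reduction(net, iterations = 2000, seed = seed)
      )
      expect_true(res$coverage_check)
      expect_gte(length(res$retained), opt)
      # minimality: removing any single retained drug breaks coverage
      for (d in res$retained) {
        if (!net$nodes$is_drug[match(d, net$nodes$id)]) next
        expect_false(coverage(net, setdiff(res$retained, d))$covered)
      }
    }
  }
})

test_that("retained size is non-increasing in the iteration budget", {
  set.seed(55)
  e <- data.frame(from = sample(12, 60, TRUE), to = 100 + sample(15, 60, TRUE))
  net <- toy_net(e$from, e$to)
  sizes <- vapply(c(10, 50, 200, 1000), function(it) {
    length(suppressWarnings(
      dominating_set_reduction(net, iterations = it, seed = 3,
                               minimality_sweep = FALSE)
    )$retained)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("skipping the sweep reproduces the literal random procedure", {
  set.seed(6)
  e <- data.frame(from = sample(8, 30, TRUE), to = 100 + sample(8, 30, TRUE))
  net <- toy_net(e$from, e$to)
  res <- suppressWarnings(
    dominating_set_reduction(net, iterations = 5, seed = 1,
                             minimality_sweep = FALSE)
  )
  expect_true(res$coverage_check)
  expect_true(is.na(res$minimal))
  expect_equal(sort(c(res$retained, res$removed)),
               sort(net$nodes$id[net$nodes$is_drug]))
})
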