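test_that("connectance is L/(R*C) with its identity cases", {
  expect_equal(connectance(bipartite_network(matrix(1, 3, 3))), 1)
  w <- matrix(c(1, 0, 2, 1, 0, 3), 2, 3)    # 4 nonzero of 6
  expect_equal(connectance(bipartite_network(w)), 4 / 6)
  expect_error(connectance(bipartite_network(matrix(c(1, 0, 0, 0), 2, 2))),
               "empty")
})

test_that("compartments counts connected components, largest first", {
  blk <- generate_perfect("block", k = 3, block_rows = 2, block_cols = 2)
  cp <- compartments(blk)
  expect_identical(cp$n, 3L)
  # one row linked to every column glues everything together
  w <- blk$weights
  w[1, ] <- 1L
  expect_identical(compartments(bipartite_network(w))$n, 1L)
  # unequal blocks: component 1 must be the bigger one
  w2 <- matrix(0L, 5, 5)
  w2[1:3, 1:3] <- 1L; w2[4:5, 4:5] <- 1L
  cp2 <- compartments(bipartite_network(w2))
  expect_identical(unname(cp2$rows), c(1L, 1L, 1L, 2L, 2L))
})

test_that("wnodf matches hand-derived cases and the tie rule", {
  expect_equal(wnodf(bipartite_network(matrix(c(2, 1, 1, 0), 2, 2, byrow = TRUE))), 1)
  expect_equal(wnodf(bipartite_network(diag(2) + 0)), 0)   # equal totals: all pairs 0
  expect_equal(wnodf(generate_perfect("nested", 5, 7)), 1)
  expect_equal(wnodf(generate_perfect("nested", 3, 3), scale = "raw"), 100)
  expect_error(wnodf(bipartite_network(matrix(5, 1, 1))), "1x1")
})

test_that("ties never increase WNODF relative to the strict structure", {
  nested <- generate_perfect("nested", 4, 4)
  tied <- bipartite_network((nested$weights > 0) + 0)   # flatten weights
  expect_lt(wnodf(tied), wnodf(nested))
})

test_that("barber_modularity matches hand-derived values", {
  n <- bipartite_network(diag(2) + 0)
  expect_equal(module_partition(c(1, 2), c(1, 2), net = n)$Q, 0.5)
  expect_equal(module_partition(c(1, 1), c(1, 1), net = n)$Q, 0)
  blk <- generate_perfect("block", k = 2, block_rows = 2, block_cols = 2)
  expect_equal(planted_partition(blk, k = 2)$Q, 0.5)
  expect_error(barber_modularity(n, module_partition(c(1, 2, 3), c(1, 2))),
               "dimensions")
})

test_that("metrics are invariant under node permutation", {
  for (rep in 1:10) {
    net <- random_hygienic_network(sample(3:6, 1), sample(3:6, 1))
    pr <- sample(nrow(net$weights)); pc <- sample(ncol(net$weights))
    pnet <- bipartite_network(net$weights[pr, pc, drop = FALSE])
    expect_equal(connectance(pnet), connectance(net))
    expect_equal(wnodf(pnet), wnodf(net))
    expect_identical(compartments(pnet)$n, compartments(net)$n)
    g <- sample(2, nrow(net$weights), replace = TRUE)
    h <- sample(2, ncol(net$weights), replace = TRUE)
    expect_equal(barber_modularity(pnet, module_partition(g[pr], h[pc])),
                 barber_modularity(net, module_partition(g, h)))
  }
})

test_that("find_modules recovers planted blocks and respects lower bounds", {
  blk <- generate_perfect("block", k = 2, block_rows = 2, block_cols = 2)
  p <- find_modules(blk, reps = 5, seed = 42)
  expect_equal(p$Q, 0.5)
  expect_identical(unname(p$row_modules), c(1L, 1L, 2L, 2L))
  expect_identical(unname(p$col_modules), c(1L, 1L, 2L, 2L))

  blk3 <- generate_perfect("block", k = 3, block_rows = 2, block_cols = 3)
  p3 <- find_modules(blk3, reps = 5, seed = 42)
  expect_identical(unname(p3$row_modules), rep(1:3, each = 2))

  one <- find_modules(bipartite_network(matrix(4, 1, 1)), reps = 1, seed = 1)
  expect_equal(one$Q, 0)
  expect_error(find_modules(blk, reps = 0), "reps")

  # never below the single-module or planted partitions; never above the
  # exhaustive optimum on tiny networks
  for (rep in 1:15) {
    net <- random_hygienic_network(sample(2:4, 1), sample(2:4, 1))
    fm <- find_modules(net, reps = 3, seed = rep)
    planted_q <- barber_modularity(net, module_partition(
      rep(1L, nrow(net$weights)), rep(1L, ncol(net$weights))))
    expect_gte(fm$Q, planted_q - 1e-12)
    n_nodes <- nrow(net$weights) + ncol(net$weights)
    best <- max(vapply(all_partitions(n_nodes), function(p) {
      barber_modularity(net, module_partition(p[seq_len(nrow(net$weights))],
                                              p[-seq_len(nrow(net$weights))]))
    }, numeric(1)))
    expect_lte(fm$Q, best + 1e-9)
  }
})

test_that("find_modules is deterministic under a seed", {
  net <- generate_network(seed = 11)$network
  p1 <- find_modules(net, reps = 4, seed = 99)
  p2 <- find_modules(net, reps = 4, seed = 99)
  expect_identical(p1$row_modules, p2$row_modules)
  expect_identical(p1$Q, p2$Q)
})

test_that("wnodf_sm restricts scoring to same-module pairs", {
  net <- random_hygienic_network(4, 5)
  single <- module_partition(rep(1L, 4), rep(1L, 5), net = net)
  expect_equal(wnodf_sm(net, single), wnodf(net))   # restriction vacuous

  # two perfectly nested blocks under the planted partition score 1
  b <- matrix(0L, 4, 4)
  b[1:2, 1:2] <- matrix(c(2, 1, 1, 0), 2, 2, byrow = TRUE)
  b[3:4, 3:4] <- matrix(c(2, 1, 1, 0), 2, 2, byrow = TRUE)
  bp <- bipartite_network(b)
  expect_equal(wnodf_sm(bp, module_partition(c(1, 1, 2, 2), c(1, 1, 2, 2))), 1)

  # all singleton modules: no same-module pair exists
  iso <- module_partition(1:4, 5:9, net = net)
  expect_true(is.na(wnodf_sm(net, iso)))
})
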