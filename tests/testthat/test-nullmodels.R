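test_that("vaznull conserves dims, links, total weight and coverage", {
  set.seed(7)
  for (rep in 1:25) {
    net <- random_hygienic_network(sample(3:7, 1), sample(3:7, 1))
    expect_valid_null(vaznull_sample(net), net)
  }
})

test_that("the fully constrained 2x2 all-ones matrix is its own null", {
  net <- bipartite_network(matrix(1, 2, 2))
  set.seed(1)
  for (rep in 1:5) expect_identical(unname(vaznull_sample(net)$weights),
                                    matrix(1L, 2, 2))
})

test_that("vaznull handles L-tight matrices where every cell must cover new species", {
  net <- bipartite_network(diag(3) * 2)    # L = 3 = R = C
  set.seed(2)
  for (rep in 1:10) expect_valid_null(vaznull_sample(net), net)
})

test_that("restricted null conserves per-region fill and weight", {
  set.seed(11)
  g <- generate_network(8, 10, 2, affinity_ratio = 20, T_events = 60, seed = 3)
  net <- g$network
  part <- find_modules(net, reps = 4, seed = 5)
  w <- net$weights
  for (rep in 1:10) {
    r <- restricted_null_sample(net, part)
    expect_valid_null(r, net)
    for (a in unique(part$row_modules)) {
      for (b in unique(part$col_modules)) {
        ri <- part$row_modules == a; ci <- part$col_modules == b
        expect_identical(sum(r$weights[ri, ci] > 0), sum(w[ri, ci] > 0))
        expect_identical(sum(r$weights[ri, ci]), sum(w[ri, ci]))
      }
    }
  }
})

test_that("a fully constrained block matrix is fixed by the restricted null", {
  blk <- generate_perfect("block", k = 2, block_rows = 2, block_cols = 2)
  part <- planted_partition(blk, k = 2)
  set.seed(3)
  expect_identical(restricted_null_sample(blk, part)$weights, blk$weights)
})

test_that("restricted nulls keep modularity near observed, vaznull degrades it", {
  g <- generate_network(10, 12, 3, affinity_ratio = 40, abundance_sd = 0.3,
                        T_events = 80, seed = 21)
  net <- g$network
  part <- find_modules(net, reps = 4, seed = 8)
  set.seed(9)
  q_restr <- replicate(15, find_modules(restricted_null_sample(net, part),
                                        reps = 2, seed = NULL)$Q)
  q_vaz <- replicate(15, find_modules(vaznull_sample(net),
                                      reps = 2, seed = NULL)$Q)
  expect_gt(mean(q_restr), mean(q_vaz))
  expect_lt(abs(mean(q_restr) - part$Q), 3 * stats::sd(q_restr) + 0.02)
})

test_that("z_score uses the sample sd and flags degenerate spread", {
  expect_equal(z_score(5, c(1, 2, 3)), 3)
  expect_equal(z_score(2, c(1, 2, 3)), 0)
  expect_true(is.na(z_score(2, c(4, 4, 4))))
  expect_error(z_score(1, 2), "at least 2")
})

test_that("null_distribution: conserved metrics have zero variance and NA z", {
  net <- generate_network(8, 8, 2, T_events = 50, seed = 2)$network
  nd_t <- null_distribution(net, "total", "vaznull", n = 30, seed = 4)
  expect_true(all(nd_t$null_values == total_weight(net)))
  expect_true(is.na(nd_t$z))
  nd_c <- null_distribution(net, "connectance", "vaznull", n = 30, seed = 4)
  expect_true(all(nd_c$null_values == connectance(net)))
})

test_that("null ensembles are bitwise reproducible under a seed", {
  net <- generate_network(8, 8, 2, T_events = 50, seed = 2)$network
  a <- null_distribution(net, "wnodf", "vaznull", n = 25, seed = 10)
  b <- null_distribution(net, "wnodf", "vaznull", n = 25, seed = 10)
  expect_identical(a$null_values, b$null_values)
  expect_identical(a$z, b$z)
})

test_that("directional sanity: planted structure yields signed z-scores", {
  # strongly nested generated matrix: WNODF above the vaznull expectation
  nested <- drop_empty(generate_perfect("nested", 8, 8))
  z_n <- null_distribution(nested, "wnodf", "vaznull", n = 60, seed = 5)
  expect_gt(z_n$z, 0)
  # strongly modular generated matrix: modularity above the vaznull expectation
  mod <- generate_network(10, 12, 3, affinity_ratio = 40, abundance_sd = 0.3,
                          T_events = 80, seed = 6)$network
  z_m <- null_distribution(mod, "modularity", "vaznull", n = 40, seed = 5,
                           reps = 2)
  expect_gt(z_m$z, 0)
})
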