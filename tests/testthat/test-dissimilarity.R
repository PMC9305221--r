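make_net <- function(bats, plants, links) {
  edge_list_to_network(data.frame(bat = links[, 1], plant = links[, 2],
                                  count = 1))
}

test_that("species_beta covers identical, partial and disjoint cases", {
  n1 <- edge_list_to_network(data.frame(bat = "A", plant = c("P1", "P2"),
                                        count = 1))
  expect_equal(species_beta(n1, n1), 0)
  n2 <- edge_list_to_network(data.frame(bat = c("A", "C"), plant = c("P1", "P3"),
                                        count = 1))
  # pooled species: {A,B?,...}; here a = |{A,P1}| = 2, b = c = 2
  n1b <- edge_list_to_network(data.frame(bat = c("A", "B"), plant = c("P1", "P2"),
                                         count = 1))
  expect_equal(species_beta(n1b, n2), 0.5)
  n3 <- edge_list_to_network(data.frame(bat = "X", plant = "Y", count = 1))
  expect_equal(species_beta(n1, n3), 1)
})

test_that("interaction_beta decomposes the worked example", {
  n1 <- edge_list_to_network(data.frame(bat = "A", plant = c("P1", "P2"), count = 1))
  n2 <- edge_list_to_network(data.frame(bat = "A", plant = c("P1", "P3"), count = 1))
  b <- interaction_beta(n1, n2)
  expect_equal(b$beta_WN, 0.5)
  expect_equal(b$beta_OS, 0)
  expect_equal(b$beta_ST, 0.5)
  expect_identical(b$shared_links, 1L)

  ident <- interaction_beta(n1, n1)
  expect_equal(ident$beta_WN, 0)
  expect_equal(ident$beta_OS, 0)
  expect_equal(ident$beta_ST, 0)
})

test_that("beta_OS is undefined when shared species have no links", {
  n1 <- edge_list_to_network(data.frame(bat = "A", plant = "P1", count = 1))
  n2 <- edge_list_to_network(data.frame(bat = "B", plant = "P2", count = 1))
  b <- interaction_beta(n1, n2)
  expect_true(is.na(b$beta_OS))
  expect_true(b$os_undefined)
  expect_equal(b$beta_ST, b$beta_WN)
  expect_equal(b$beta_WN, 1)
})

test_that("beta components are symmetric, bounded and weight-blind", {
  set.seed(5)
  for (rep in 1:30) {
    n1 <- random_pool_network(paste0("b", 1:6), paste0("p", 1:8))
    n2 <- random_pool_network(paste0("b", 1:6), paste0("p", 1:8))
    b12 <- interaction_beta(n1, n2)
    b21 <- interaction_beta(n2, n1)
    expect_equal(b12$beta_WN, b21$beta_WN)
    expect_equal(b12$beta_OS, b21$beta_OS)
    expect_equal(b12$beta_S, b21$beta_S)
    for (v in c(b12$beta_S, b12$beta_WN, b12$beta_ST)) {
      expect_gte(v, -1e-12); expect_lte(v, 1 + 1e-12)
    }
    # doubling all weights changes nothing: links are binarized
    n1h <- bipartite_network(n1$weights * 2L)
    expect_equal(interaction_beta(n1h, n2)$beta_WN, b12$beta_WN)
  }
})

test_that("beta_table builds the requested comparisons", {
  nets <- list(a = random_pool_network(paste0("b", 1:5), paste0("p", 1:6)),
               b = random_pool_network(paste0("b", 1:5), paste0("p", 1:6)),
               c = random_pool_network(paste0("b", 1:5), paste0("p", 1:6)))
  tab <- beta_table(nets)
  expect_identical(nrow(tab), 3L)      # all unordered pairs
  self <- beta_table(nets, pairs = list(c("a", "a")))
  expect_equal(self$beta_WN, 0)
  expect_equal(self$beta_S, 0)
  rev <- beta_table(nets, pairs = list(c("b", "a")))
  fwd <- beta_table(nets, pairs = list(c("a", "b")))
  expect_equal(rev$beta_WN, fwd$beta_WN)
  expect_error(beta_table(nets, pairs = list(c("a", "zzz"))), "unknown")
})

test_that("planted rewiring drives beta_OS with no turnover signal", {
  sp <- generate_season_pair(rho = 0.5, tau = 0, seed = 31)
  b <- interaction_beta(sp$net_A, sp$net_B)
  expect_gt(b$beta_OS, 0)
  expect_lt(abs(b$beta_ST), 0.15)      # drop_empty can shave a species or two
  sp0 <- generate_season_pair(rho = 0, tau = 0, seed = 31)
  expect_equal(interaction_beta(sp0$net_A, sp0$net_B)$beta_WN, 0)
})

test_that("full turnover removes shared species", {
  sp <- generate_season_pair(R = 8, C = 10, rho = 0, tau = 1, seed = 13)
  b <- interaction_beta(sp$net_A, sp$net_B)
  expect_true(is.na(b$beta_OS))
  expect_equal(b$beta_S, 1)
})
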