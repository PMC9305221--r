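# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately use naive element-by-element loops so they share no code
# path with the package implementation.

# WNODF by direct enumeration of the definition: for each ordered pair with a
# strictly larger marginal total, the share of the poorer line's occupied
# cells that are strictly smaller than the richer line's. Unit (0-1) scale.
oracle_wnodf <- function(w) {
  pair_scores <- function(mat) {
    n <- nrow(mat)
    scores <- numeric(0)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (sum(mat[i, ]) > sum(mat[j, ])) {
          occupied <- 0L; smaller <- 0L
          for (cc in seq_len(ncol(mat))) {
            if (mat[j, cc] > 0) {
              occupied <- occupied + 1L
              if (mat[j, cc] < mat[i, cc]) smaller <- smaller + 1L
            }
          }
          scores <- c(scores, 100 * smaller / occupied)
        }
      }
    }
    scores
  }
  denom <- nrow(w) * (nrow(w) - 1) / 2 + ncol(w) * (ncol(w) - 1) / 2
  (sum(pair_scores(w)) + sum(pair_scores(t(w)))) / denom / 100
}

# Barber modularity by the double loop over all cells.
oracle_barber_q <- function(w, g, h) {
  Tw <- sum(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (g[i] == h[j]) {
        q <- q + w[i, j] - sum(w[i, ]) * sum(w[, j]) / Tw
      }
    }
  }
  q / Tw
}

# All set partitions of n elements as restricted-growth strings (module id
# vectors). Cached per n; Bell(8) = 4140.
.partition_cache <- new.env(parent = emptyenv())
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    k <- max(prefix)
    out <- list()
    for (lab in seq_len(k + 1L)) out <- c(out, grow(c(prefix, lab)))
    out
  }
  res <- grow(1L)
  .partition_cache[[key]] <- res
  res
}

# Random hygienic count matrix with every margin positive.
random_hygienic_matrix <- function(R, C, max_w = 4L) {
  w <- matrix(sample(0:max_w, R * C, replace = TRUE,
                     prob = c(0.45, rep(0.55 / max_w, max_w))), R, C)
  for (i in which(rowSums(w) == 0)) w[i, sample(C, 1L)] <- sample(max_w, 1L)
  for (j in which(colSums(w) == 0)) w[sample(R, 1L), j] <- sample(max_w, 1L)
  w
}

random_hygienic_network <- function(R, C, max_w = 4L) {
  bipartite_network(random_hygienic_matrix(R, C, max_w))
}

# Random network over a shared label pool (for beta-diversity pair tests).
random_pool_network <- function(pool_bats, pool_plants) {
  nb <- sample(2:length(pool_bats), 1L)
  np <- sample(2:length(pool_plants), 1L)
  bats <- sample(pool_bats, nb)
  plants <- sample(pool_plants, np)
  w <- random_hygienic_matrix(nb, np, max_w = 3L)
  bipartite_network(w, row_labels = bats, col_labels = plants)
}

# Monte-Carlo subsampling oracle for individual-based rarefaction.
mc_rarefaction <- function(counts, n, draws = 10000L) {
  events <- rep(seq_along(counts), counts)
  richness <- replicate(draws, length(unique(sample(events, n))))
  list(mean = mean(richness), se = stats::sd(richness) / sqrt(draws))
}

expect_valid_null <- function(null_net, obs_net) {
  wo <- obs_net$weights; wn <- null_net$weights
  expect_identical(dim(wn), dim(wo))
  expect_identical(sum(wn > 0), sum(wo > 0))
  expect_identical(sum(wn), sum(wo))
  expect_true(all(rowSums(wn) > 0))
  expect_true(all(colSums(wn) > 0))
  expect_true(all(wn >= 0))
}
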