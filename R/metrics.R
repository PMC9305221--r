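#' Connectance of a bipartite network
#'
#' The realised fraction of possible links, L / (R * C).
#'
#' @param net a hygienic `bipartite_network` (all margins positive).
#' @return a number in (0, 1].
#' @export
connectance <- function(net) {
  assert_hygienic(net)
  w <- as_weights(net)
  sum(w > 0L) / (nrow(w) * ncol(w))
}

#' Compartments (connected components) of a network
#'
#' A compartment is an isolated subset of nodes that interact with each other
#' but have no link to the rest of the network. Components are relabelled by
#' decreasing size (ties broken by the smallest row index they contain).
#'
#' @param net a hygienic `bipartite_network`.
#' @return list with `n` (number of compartments), `rows` and `cols` (integer
#'   component id per row/column node, named by taxon).
#' @export
compartments <- function(net) {
  assert_hygienic(net)
  w <- as_weights(net)
  R <- nrow(w); C <- ncol(w)
  g <- igraph::graph_from_biadjacency_matrix(w > 0L)
  memb <- igraph::components(g)$membership
  rows <- memb[seq_len(R)]
  cols <- memb[R + seq_len(C)]
  sizes <- table(memb)
  first_row <- vapply(names(sizes), function(id) {
    hit <- which(rows == as.integer(id))
    if (length(hit)) min(hit) else R + min(which(cols == as.integer(id)))
  }, numeric(1))
  ord <- order(-as.integer(sizes), first_row)
  relab <- integer(length(sizes))
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  rows <- stats::setNames(relab[rows], rownames(w))
  cols <- stats::setNames(relab[cols], colnames(w))
  list(n = length(sizes), rows = rows, cols = cols)
}

# Sum of WNODF pair scores for the rows of `mat`, plus the number of ordered
# pairs considered, restricted to pairs in the same group when `groups` given.
# Pair (i, j) scores 100 * #{c: 0 < mat[j,c] < mat[i,c]} / #{c: mat[j,c] > 0}
# when marginal total i > marginal total j; equal totals score 0.
wnodf_pair_sum <- function(mat, groups = NULL) {
  n <- nrow(mat)
  if (n < 2L) return(c(sum = 0, pairs = 0))
  mt <- rowSums(mat)
  s <- 0; npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.null(groups) && groups[i] != groups[j]) next
      npairs <- npairs + 1L
      if (mt[i] == mt[j]) next
      hi <- if (mt[i] > mt[j]) i else j
      lo <- if (mt[i] > mt[j]) j else i
      occ <- mat[lo, ] > 0
      s <- s + 100 * sum(occ & mat[lo, ] < mat[hi, ]) / sum(occ)
    }
  }
  c(sum = s, pairs = npairs)
}

#' Weighted nestedness (WNODF)
#'
#' Weighted NODF of Almeida-Neto & Ulrich (2011): for every pair of rows the
#' one with the smaller marginal total contributes the percentage of its
#' occupied cells whose weights are strictly smaller than the corresponding
#' cells of the richer row; pairs with equal marginal totals contribute zero
#' (the decreasing-fill rule). Likewise for columns. The index is the mean
#' over all row and column pairs.
#'
#' @param net a hygienic `bipartite_network`.
#' @param scale `"unit"` (default) rescales the classic 0-100 index to 0-1;
#'   `"raw"` returns the 0-100 value.
#' @return nestedness on the requested scale.
#' @export
wnodf <- function(net, scale = c("unit", "raw")) {
  scale <- match.arg(scale)
  assert_hygienic(net)
  w <- as_weights(net)
  if (nrow(w) < 2L && ncol(w) < 2L) {
    stop("WNODF is undefined for a 1x1 network", call. = FALSE)
  }
  pr <- wnodf_pair_sum(w)
  pc <- wnodf_pair_sum(t(w))
  raw <- (pr["sum"] + pc["sum"]) / (pr["pairs"] + pc["pairs"])
  unname(if (scale == "raw") raw else raw / 100)
}

#' Create a module partition
#'
#' Joint assignment of row and column nodes to modules. Module ids live in a
#' single shared label space: a row and a column are in the same module iff
#' their ids are equal.
#'
#' @param row_modules,col_modules integer module ids, one per row/column node.
#' @param net optional network used to attach labels and a Barber Q score.
#' @return an object of class `module_partition` with elements `row_modules`,
#'   `col_modules` and `Q` (NA unless `net` given).
#' @export
module_partition <- function(row_modules, col_modules, net = NULL) {
  p <- structure(list(row_modules = as.integer(row_modules),
                      col_modules = as.integer(col_modules),
                      Q = NA_real_),
                 class = "module_partition")
  if (!is.null(net)) {
    w <- as_weights(net)
    if (length(p$row_modules) != nrow(w) || length(p$col_modules) != ncol(w)) {
      stop("partition does not match network dimensions", call. = FALSE)
    }
    names(p$row_modules) <- rownames(w)
    names(p$col_modules) <- colnames(w)
    p$Q <- barber_modularity(net, p)
  }
  p
}

#' @export
print.module_partition <- function(x, ...) {
  m <- length(unique(c(x$row_modules, x$col_modules)))
  cat(sprintf("<module_partition> %d modules over %d + %d nodes, Q = %s\n",
              m, length(x$row_modules), length(x$col_modules),
              format(x$Q, digits = 4)))
  invisible(x)
}

#' Barber modularity of a partition
#'
#' Q = (1/T) * sum_ij (A_ij - k_i d_j / T) * 1[g_i = h_j], where T is the
#' total weight, k_i and d_j the marginal totals, and g, h the module ids of
#' rows and columns. Reported unnormalised, as returned by weighted bipartite
#' modularity optimisers.
#'
#' @param net a `bipartite_network` (or weight matrix).
#' @param partition a `module_partition` indexing `net`.
#' @return the modularity score Q.
#' @export
barber_modularity <- function(net, partition) {
  w <- as_weights(net)
  g <- partition$row_modules
  h <- partition$col_modules
  if (length(g) != nrow(w) || length(h) != ncol(w)) {
    stop("partition does not match network dimensions", call. = FALSE)
  }
  Tw <- sum(w)
  B <- w - outer(rowSums(w), colSums(w)) / Tw
  sum(B[outer(g, h, "==")]) / Tw
}

# --- DIRTLPAwb+ ---------------------------------------------------------------

# One sweep of weighted label propagation for one guild. B is the modularity
# matrix; own = current labels of the guild being updated (length n), other =
# labels of the opposite guild. Each node adopts the opposite-guild label with
# the largest positive summed B over matching partners; if no label helps it
# keeps (or is given) a label unique to itself. Ties go to the smallest label.
lpa_sweep <- function(B_own_by_other, own, other, fresh_base) {
  labs <- sort(unique(other))
  gains <- t(rowsum(t(B_own_by_other), group = other))  # n x length(labs)
  colnames(gains) <- as.character(labs)
  new <- own
  for (i in seq_along(own)) {
    gi <- gains[i, ]
    best <- which.max(gi)          # first max = smallest label id
    if (gi[best] > 0) {
      new[i] <- labs[best]
    } else if (!(own[i] %in% other) && sum(own == own[i]) == 1L) {
      # already alone in its own module; keep it
    } else {
      new[i] <- fresh_base + i     # retreat to a singleton module
    }
  }
  new
}

partition_Q <- function(B, Tw, g, h) sum(B[outer(g, h, "==")]) / Tw

# Label propagation until Q stops improving.
lpa_converge <- function(B, Tw, g, h, tol = 1e-10) {
  n_r <- nrow(B); n_c <- ncol(B)
  q <- partition_Q(B, Tw, g, h)
  repeat {
    g2 <- lpa_sweep(B, g, h, fresh_base = 2L * (n_r + n_c))
    h2 <- lpa_sweep(t(B), h, g2, fresh_base = 3L * (n_r + n_c))
    q2 <- partition_Q(B, Tw, g2, h2)
    if (q2 > q + tol) {
      g <- g2; h <- h2; q <- q2
    } else {
      break
    }
  }
  list(g = g, h = h, Q = q)
}

# Greedy agglomeration: merge the module pair with the largest positive
# joint-gain, re-run propagation, repeat until no merge improves Q.
agglomerate <- function(B, Tw, g, h, tol = 1e-10) {
  repeat {
    labs <- sort(unique(c(g, h)))
    if (length(labs) < 2L) break
    m <- length(labs)
    # W[a, b] = sum of B over rows in module a, cols in module b (zero when a
    # module has no members in a guild)
    Ig <- matrix(0, nrow(B), m); Ig[cbind(seq_along(g), match(g, labs))] <- 1
    Ih <- matrix(0, ncol(B), m); Ih[cbind(seq_along(h), match(h, labs))] <- 1
    W <- t(Ig) %*% B %*% Ih
    S <- W + t(W)
    diag(S) <- -Inf
    best <- arrayInd(which.max(S), dim(S))
    if (S[best] <= tol) break
    a <- labs[best[1L]]; b <- labs[best[2L]]
    g[g == b] <- a
    h[h == b] <- a
    res <- lpa_converge(B, Tw, g, h, tol)
    g <- res$g; h <- res$h
  }
  list(g = g, h = h, Q = partition_Q(B, Tw, g, h))
}

# Relabel modules 1..m by decreasing within-module link weight, ties by the
# smallest member node index (rows first).
canonicalize_partition <- function(w, g, h) {
  labs <- unique(c(g, h))
  within <- vapply(labs, function(m) sum(w[g == m, h == m, drop = FALSE]),
                   numeric(1))
  first <- vapply(labs, function(m) {
    r <- which(g == m); c <- which(h == m)
    min(c(r, nrow(w) + c))
  }, numeric(1))
  ord <- order(-within, first)
  relab <- stats::setNames(seq_along(labs), labs[ord])
  list(g = unname(relab[as.character(g)]), h = unname(relab[as.character(h)]))
}

#' Find modules with DIRTLPAwb+
#'
#' Maximises Barber modularity with the DIRTLPAwb+ strategy: weighted label
#' propagation alternating between guilds until Q stops improving (LPAwb+
#' stage 1), greedy agglomeration of module pairs with propagation re-run
#' after each merge (stage 2), the whole procedure restarted from random
#' initial labelings with different initial module counts (the DIRT wrapper),
#' keeping the partition with the greatest Q. Deterministic given
#' `(net, reps, seed)`.
#'
#' @param net a hygienic `bipartite_network`.
#' @param reps random restarts per initial module count (default 10).
#' @param seed integer seed driving all restarts; `NULL` uses the session RNG.
#' @param tol convergence tolerance on Q improvements.
#' @return a canonicalised `module_partition` with its Q.
#' @references Beckett (2016) Improved community detection in weighted
#'   bipartite networks. R. Soc. Open Sci. 3:140536.
#' @export
find_modules <- function(net, reps = 10L, seed = NULL, tol = 1e-10) {
  assert_hygienic(net)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  w <- as_weights(net)
  R <- nrow(w); C <- ncol(w)
  Tw <- sum(w)
  B <- w - outer(rowSums(w), colSums(w)) / Tw

  run_from <- function(g0, h0) {
    res <- lpa_converge(B, Tw, g0, h0, tol)
    agglomerate(B, Tw, res$g, res$h, tol)
  }

  with_seed(seed, {
    # deterministic baseline: every row its own module, columns join by sweep
    best <- run_from(seq_len(R), rep(0L, C))
    kmax <- min(R, C)
    ks <- unique(c(2^(0:floor(log2(max(kmax, 1)))), kmax))
    for (k in ks) {
      for (rep in seq_len(reps)) {
        g0 <- sample.int(k, R, replace = TRUE)
        h0 <- sample.int(k, C, replace = TRUE)
        cand <- run_from(g0, h0)
        if (cand$Q > best$Q + tol) best <- cand
      }
    }
    canon <- canonicalize_partition(w, best$g, best$h)
    p <- module_partition(canon$g, canon$h, net = net)
    p
  })
}

#' Within-module weighted nestedness (WNODF_SM)
#'
#' WNODF restricted to pairs of rows assigned to the same module and pairs of
#' columns assigned to the same module — the nestedness component of a
#' compound (modular with internally nested modules) topology.
#'
#' @param net a hygienic `bipartite_network`.
#' @param partition a `module_partition` for `net`, normally the best
#'   partition from [find_modules()].
#' @param scale `"unit"` (0-1, default) or `"raw"` (0-100).
#' @return nestedness among same-module pairs; `NA` if no two rows and no two
#'   columns share a module.
#' @export
wnodf_sm <- function(net, partition, scale = c("unit", "raw")) {
  scale <- match.arg(scale)
  assert_hygienic(net)
  w <- as_weights(net)
  g <- partition$row_modules
  h <- partition$col_modules
  if (length(g) != nrow(w) || length(h) != ncol(w)) {
    stop("partition does not match network dimensions", call. = FALSE)
  }
  pr <- wnodf_pair_sum(w, groups = g)
  pc <- wnodf_pair_sum(t(w), groups = h)
  if (pr["pairs"] + pc["pairs"] == 0) return(NA_real_)
  raw <- (pr["sum"] + pc["sum"]) / (pr["pairs"] + pc["pairs"])
  unname(if (scale == "raw") raw else raw / 100)
}
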