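#' Generate a synthetic bat-plant interaction network
#'
#' Emulates a molecular diet matrix: species carry lognormal abundance
#' weights (skewed marginals create supergeneralists), affinity is boosted
#' within planted modules (block-modular structure), and `T_events`
#' individual detection events are drawn from the resulting categorical cell
#' distribution, giving integer counts. The matrix is passed through
#' [drop_empty()], so rare species may be absent from the realized network.
#'
#' The defaults mirror a single-forest whole-year study network: 12 bat and
#' 22 plant taxa, 3 modules, and 130 detection events.
#'
#' @param R,C numbers of bat and plant taxa before hygiene.
#' @param n_modules planted module count (round-robin species assignment).
#' @param affinity_ratio multiplicative preference for same-module partners;
#'   1 = no modular structure.
#' @param abundance_sd sd of the lognormal abundance weights; 0 = equal
#'   abundances, larger values skew the marginals and induce nestedness.
#' @param T_events total number of detection events (total weight before
#'   hygiene).
#' @param seed integer seed; same arguments + seed give identical output.
#' @return list with `network` (a hygienic `bipartite_network`) and `truth`
#'   (planted module labels, abundances and parameters, sufficient to
#'   recompute the cell probabilities).
#' @export
generate_network <- function(R = 12L, C = 22L, n_modules = 3L,
                             affinity_ratio = 30, abundance_sd = 0.7,
                             T_events = 130L, seed = NULL) {
  if (n_modules < 1L || R < n_modules || C < n_modules) {
    stop("need R >= n_modules >= 1 and C >= n_modules", call. = FALSE)
  }
  if (T_events < max(R, C)) {
    stop("T_events must be >= max(R, C)", call. = FALSE)
  }
  if (affinity_ratio < 0 || abundance_sd < 0) {
    stop("affinity_ratio and abundance_sd must be nonnegative", call. = FALSE)
  }
  with_seed(seed, {
    row_mod <- ((seq_len(R) - 1L) %% n_modules) + 1L
    col_mod <- ((seq_len(C) - 1L) %% n_modules) + 1L
    a_r <- stats::rlnorm(R, 0, abundance_sd)
    a_c <- stats::rlnorm(C, 0, abundance_sd)
    p <- outer(a_r, a_c) * ifelse(outer(row_mod, col_mod, "=="),
                                  affinity_ratio, 1)
    p <- p / sum(p)
    ev <- sample.int(R * C, T_events, replace = TRUE, prob = p)
    w <- matrix(tabulate(ev, nbins = R * C), R, C)
    rownames(w) <- paste0("bat", seq_len(R))
    colnames(w) <- paste0("plant", seq_len(C))
    net <- drop_empty(bipartite_network(w, meta = list(origin = "synthetic")))
    truth <- list(row_modules = stats::setNames(row_mod, rownames(w)),
                  col_modules = stats::setNames(col_mod, colnames(w)),
                  row_abundance = stats::setNames(a_r, rownames(w)),
                  col_abundance = stats::setNames(a_c, colnames(w)),
                  affinity_ratio = affinity_ratio,
                  abundance_sd = abundance_sd,
                  n_modules = n_modules, T_events = T_events, seed = seed)
    list(network = net, truth = truth)
  })
}

#' Generate idealized fixture networks
#'
#' `kind = "nested"` returns the perfectly nested staircase matrix with
#' weights `max(0, (R - i) + (C - j))`, whose WNODF is exactly 1;
#' `kind = "block"` returns `k` disjoint all-ones blocks, which has exactly
#' `k` compartments and, for two equal blocks, Barber modularity 0.5 under
#' the planted partition.
#'
#' @param kind `"nested"` or `"block"`.
#' @param R,C dimensions for the nested matrix (both >= 2).
#' @param k number of blocks.
#' @param block_rows,block_cols dimensions of each block.
#' @return a `bipartite_network`.
#' @export
generate_perfect <- function(kind = c("nested", "block"), R = 4L, C = 4L,
                             k = 2L, block_rows = 2L, block_cols = 2L) {
  kind <- match.arg(kind)
  if (kind == "nested") {
    if (R < 2L || C < 2L) stop("nested fixture needs R, C >= 2", call. = FALSE)
    w <- outer(seq_len(R), seq_len(C), function(i, j) pmax(0L, (R - i) + (C - j)))
    return(bipartite_network(w, meta = list(origin = "perfect_nested")))
  }
  if (k < 1L || block_rows < 1L || block_cols < 1L) {
    stop("block fixture needs k, block_rows, block_cols >= 1", call. = FALSE)
  }
  w <- matrix(0L, k * block_rows, k * block_cols)
  for (b in seq_len(k)) {
    w[(b - 1L) * block_rows + seq_len(block_rows),
      (b - 1L) * block_cols + seq_len(block_cols)] <- 1L
  }
  bipartite_network(w, meta = list(origin = "perfect_block"))
}

#' Planted partition of a block fixture or synthetic truth
#'
#' Convenience: the module partition that assigns each block (or each planted
#' synthetic module) its own id, restricted to the network's surviving
#' species.
#'
#' @param net a `bipartite_network` whose labels appear in `truth`.
#' @param truth either the `truth` element of [generate_network()] output, or
#'   `NULL` for a [generate_perfect()] block fixture (block structure is
#'   inferred from dimensions and `k`).
#' @param k block count when `truth` is `NULL`.
#' @return a `module_partition` scored on `net`.
#' @export
planted_partition <- function(net, truth = NULL, k = 2L) {
  w <- as_weights(net)
  if (!is.null(truth)) {
    g <- truth$row_modules[rownames(w)]
    h <- truth$col_modules[colnames(w)]
    if (anyNA(g) || anyNA(h)) stop("network labels not found in truth", call. = FALSE)
    return(module_partition(g, h, net = net))
  }
  br <- nrow(w) / k; bc <- ncol(w) / k
  if (br != round(br) || bc != round(bc)) {
    stop("dimensions are not divisible into k equal blocks", call. = FALSE)
  }
  module_partition(rep(seq_len(k), each = br), rep(seq_len(k), each = bc),
                   net = net)
}

#' Generate a paired pair of seasonal networks with planted change
#'
#' Produces a base network and a derived "second season": a fraction `tau` of
#' each guild is replaced by fresh species (species turnover, each
#' replacement inheriting the link degree of the species it replaces), and a
#' fraction `rho` of the links among the retained (shared) species is rewired
#' by moving the plant endpoint to a different shared plant (avoiding
#' duplicate links). Counts in the second network are resampled by
#' distributing `T_events` over its links proportional to abundance weights,
#' with every link keeping at least one event.
#'
#' @inheritParams generate_network
#' @param rho rewiring fraction among shared-species links, in `[0, 1]`.
#' @param tau species-turnover fraction per guild, in `[0, 1]`.
#' @return list with `net_A`, `net_B` (hygienic `bipartite_network`s) and
#'   `truth` (planted `rho`, `tau`, replaced labels, rewired link count,
#'   plus the base network's truth).
#' @export
generate_season_pair <- function(R = 12L, C = 22L, n_modules = 3L,
                                 affinity_ratio = 30, abundance_sd = 0.7,
                                 T_events = 130L, rho = 0, tau = 0,
                                 seed = NULL) {
  if (rho < 0 || rho > 1 || tau < 0 || tau > 1) {
    stop("rho and tau must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    base <- generate_network(R, C, n_modules, affinity_ratio, abundance_sd,
                             T_events, seed = NULL)
    net_a <- base$network
    wa <- as_weights(net_a)
    edges <- as_edge_list(net_a)      # bat, plant, count

    bats <- rownames(wa); plants <- colnames(wa)
    n_rep_b <- round(tau * length(bats))
    n_rep_p <- round(tau * length(plants))
    rep_bats <- if (n_rep_b > 0) sort(sample(bats, n_rep_b)) else character(0)
    rep_plants <- if (n_rep_p > 0) sort(sample(plants, n_rep_p)) else character(0)
    shared_bats <- setdiff(bats, rep_bats)
    shared_plants <- setdiff(plants, rep_plants)

    deg_bat <- table(edges$bat)
    deg_plant <- table(edges$plant)

    # links among retained species survive into season B
    keep <- edges$bat %in% shared_bats & edges$plant %in% shared_plants
    links <- edges[keep, c("bat", "plant")]

    # rewiring: move the plant endpoint of a fraction rho of shared links
    n_rw_target <- round(rho * nrow(links))
    if (n_rw_target > 0 && length(shared_plants) < 2L) {
      stop("rewiring infeasible: fewer than two shared plants", call. = FALSE)
    }
    n_rw <- 0L
    if (n_rw_target > 0) {
      sel <- sample(nrow(links), n_rw_target)
      for (i in sel) {
        cand <- setdiff(shared_plants, links$plant[links$bat == links$bat[i]])
        if (length(cand)) {
          links$plant[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
          n_rw <- n_rw + 1L
        }
      }
    }

    # turnover: fresh species inherit the degree of the one they replace and
    # choose partners by abundance among season-B species
    new_bats <- if (n_rep_b > 0) paste0("bat_new", seq_len(n_rep_b)) else character(0)
    new_plants <- if (n_rep_p > 0) paste0("plant_new", seq_len(n_rep_p)) else character(0)
    all_plants_b <- c(shared_plants, new_plants)
    all_bats_b <- c(shared_bats, new_bats)
    a_c_b <- c(base$truth$col_abundance[shared_plants],
               stats::setNames(stats::rlnorm(n_rep_p, 0, abundance_sd), new_plants))
    a_r_b <- c(base$truth$row_abundance[shared_bats],
               stats::setNames(stats::rlnorm(n_rep_b, 0, abundance_sd), new_bats))
    for (i in seq_along(new_bats)) {
      d <- min(unname(deg_bat[rep_bats[i]]), length(all_plants_b))
      tgt <- sample(all_plants_b, d, prob = a_c_b[all_plants_b])
      links <- rbind(links, data.frame(bat = new_bats[i], plant = tgt))
    }
    for (i in seq_along(new_plants)) {
      d <- min(unname(deg_plant[rep_plants[i]]), length(all_bats_b))
      src <- sample(all_bats_b, d, prob = a_r_b[all_bats_b])
      add <- data.frame(bat = src, plant = new_plants[i])
      add <- add[!paste(add$bat, add$plant) %in% paste(links$bat, links$plant), ,
                 drop = FALSE]
      links <- rbind(links, add)
    }
    links <- unique(links)
    if (nrow(links) == 0L) stop("season pair infeasible: no links left",
                                call. = FALSE)

    # resample counts: one event per link, remainder by abundance product
    pr <- a_r_b[links$bat] * a_c_b[links$plant]
    cnt <- rep(1L, nrow(links))
    extra <- T_events - nrow(links)
    if (extra > 0L) {
      ev <- sample(nrow(links), extra, replace = TRUE, prob = pr)
      cnt <- cnt + tabulate(ev, nbins = nrow(links))
    }
    net_b <- edge_list_to_network(
      data.frame(bat = links$bat, plant = links$plant, count = cnt),
      meta = list(origin = "synthetic_season_B"))

    truth <- c(base$truth,
               list(rho = rho, tau = tau,
                    replaced_bats = rep_bats, replaced_plants = rep_plants,
                    n_rewired = n_rw, pair_seed = seed))
    list(net_A = net_a, net_B = net_b, truth = truth)
  })
}
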