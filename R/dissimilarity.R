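# Guild-tagged species and link identity sets. Links are binarized: a link is
# the (bat, plant) label pair, regardless of weight.
species_set <- function(net) {
  w <- as_weights(net)
  c(paste0("bat:", rownames(w)), paste0("plant:", colnames(w)))
}

link_set <- function(net) {
  e <- as_edge_list(net)
  paste(e$bat, e$plant, sep = " -> ")
}

sorensen <- function(set1, set2) {
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  c <- length(setdiff(set2, set1))
  if (a + b + c == 0L) return(NA_real_)
  (b + c) / (2 * a + b + c)
}

#' Species-composition dissimilarity between two networks
#'
#' Soerensen dissimilarity beta_S = (b + c) / (2a + b + c) over the pooled
#' species sets of both guilds, where a counts species present in both
#' networks and b, c those unique to each. Matching is by exact (trimmed)
#' label within guild.
#'
#' @param net1,net2 hygienic `bipartite_network`s with comparable labels.
#' @return beta_S in `[0, 1]`.
#' @export
species_beta <- function(net1, net2) {
  sorensen(species_set(net1), species_set(net2))
}

#' Decompose interaction dissimilarity into rewiring and turnover
#'
#' The Poisot et al. (2012) framework: beta_WN is the Soerensen dissimilarity
#' of the two full link sets; beta_OS the dissimilarity of the link sets of
#' the subnetworks induced on species occurring in both networks (so it
#' captures rewiring among shared species); and beta_ST = beta_WN - beta_OS
#' is the part of interaction dissimilarity driven by species turnover.
#' Links are binary (weights ignored).
#'
#' When the shared-species subnetworks hold no links in either network,
#' beta_OS is undefined (`NA`) and beta_ST is reported equal to beta_WN with
#' `os_undefined = TRUE`.
#'
#' @param net1,net2 hygienic `bipartite_network`s.
#' @return an object of class `beta_report`: list with `beta_S`, `beta_WN`,
#'   `beta_OS`, `beta_ST`, `os_undefined`, `shared_species` (guild-tagged
#'   labels), `shared_links` (count), and per-guild shared/unique counts.
#' @export
interaction_beta <- function(net1, net2) {
  w1 <- as_weights(net1); w2 <- as_weights(net2)
  ls1 <- link_set(net1); ls2 <- link_set(net2)
  beta_wn <- sorensen(ls1, ls2)

  shared_bats <- intersect(rownames(w1), rownames(w2))
  shared_plants <- intersect(colnames(w1), colnames(w2))
  induced <- function(w) {
    sb <- intersect(rownames(w), shared_bats)
    sp <- intersect(colnames(w), shared_plants)
    if (!length(sb) || !length(sp)) return(character(0))
    e <- which(w[sb, sp, drop = FALSE] > 0L, arr.ind = TRUE)
    paste(sb[e[, 1L]], sp[e[, 2L]], sep = " -> ")
  }
  il1 <- induced(w1); il2 <- induced(w2)
  if (!length(il1) && !length(il2)) {
    beta_os <- NA_real_
    beta_st <- beta_wn
    os_undef <- TRUE
  } else {
    beta_os <- sorensen(il1, il2)
    beta_st <- beta_wn - beta_os
    os_undef <- FALSE
  }
  structure(list(
    beta_S = species_beta(net1, net2),
    beta_WN = beta_wn,
    beta_OS = beta_os,
    beta_ST = beta_st,
    os_undefined = os_undef,
    shared_species = c(paste0("bat:", shared_bats), paste0("plant:", shared_plants)),
    shared_links = length(intersect(ls1, ls2)),
    guild_counts = list(
      bats = c(shared = length(shared_bats),
               only1 = nrow(w1) - length(shared_bats),
               only2 = nrow(w2) - length(shared_bats)),
      plants = c(shared = length(shared_plants),
                 only1 = ncol(w1) - length(shared_plants),
                 only2 = ncol(w2) - length(shared_plants)))),
    class = "beta_report")
}

#' @export
print.beta_report <- function(x, ...) {
  cat(sprintf("<beta_report> beta_S = %.3f, beta_WN = %.3f, beta_OS = %s, beta_ST = %.3f%s\n",
              x$beta_S, x$beta_WN,
              ifelse(is.na(x$beta_OS), "NA", sprintf("%.3f", x$beta_OS)),
              x$beta_ST,
              if (x$os_undefined) " [beta_OS undefined: no shared-species links]" else ""))
  invisible(x)
}

#' Pairwise beta-diversity table for a set of networks
#'
#' @param networks named list of hygienic `bipartite_network`s.
#' @param pairs list of length-2 character vectors naming the comparisons;
#'   default: all unordered pairs.
#' @return a data frame with one row per pair: `net1`, `net2`, `beta_S`,
#'   `beta_WN`, `beta_OS`, `beta_ST`, `shared_species`, `shared_links`.
#' @export
beta_table <- function(networks, pairs = NULL) {
  if (length(networks) < 2L) stop("need at least two networks", call. = FALSE)
  if (is.null(names(networks)) || anyDuplicated(names(networks))) {
    stop("networks must be uniquely named", call. = FALSE)
  }
  if (is.null(pairs)) {
    nm <- names(networks)
    pairs <- utils::combn(nm, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(networks))) {
      stop("unknown network label: ", paste(setdiff(pr, names(networks)),
                                            collapse = ", "), call. = FALSE)
    }
    b <- interaction_beta(networks[[pr[1L]]], networks[[pr[2L]]])
    data.frame(net1 = pr[1L], net2 = pr[2L], beta_S = b$beta_S,
               beta_WN = b$beta_WN, beta_OS = b$beta_OS, beta_ST = b$beta_ST,
               shared_species = length(b$shared_species),
               shared_links = b$shared_links, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
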