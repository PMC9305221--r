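#' Chao1 richness estimate
#'
#' Nonparametric lower-bound richness estimator from singleton and doubleton
#' counts. With S_obs observed classes, f1 singletons and f2 doubletons:
#' classic = S_obs + f1^2 / (2 f2); bias-corrected =
#' S_obs + f1 (f1 - 1) / (2 (f2 + 1)). The classic form is undefined at
#' f2 = 0 and falls back to the bias-corrected form (flagged via the
#' `"fallback"` attribute).
#'
#' @param abundances positive integer abundance per observed class.
#' @param variant `"classic"` (default) or `"bias_corrected"`.
#' @return the estimate (>= S_obs), with attributes `variant` (the formula
#'   actually applied) and `fallback` (logical).
#' @export
chao1 <- function(abundances, variant = c("classic", "bias_corrected")) {
  variant <- match.arg(variant)
  if (length(abundances) < 1L || any(abundances <= 0) ||
      any(abundances != round(abundances))) {
    stop("abundances must be positive integers", call. = FALSE)
  }
  s_obs <- length(abundances)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  fallback <- FALSE
  if (variant == "classic" && f2 == 0) {
    variant <- "bias_corrected"
    fallback <- TRUE
  }
  est <- if (variant == "classic") s_obs + f1^2 / (2 * f2)
         else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  structure(est, variant = variant, fallback = fallback)
}

#' Sampling completeness of a network
#'
#' Treats each realised link as a class and its cell count (number of
#' detection events) as the class abundance, then reports the observed
#' fraction of the Chao1-estimated link richness as a percentage:
#' 100 * L / Chao1.
#'
#' @param net a hygienic `bipartite_network`.
#' @param variant Chao1 variant, see [chao1()].
#' @return completeness percentage in (0, 100].
#' @export
network_completeness <- function(net, variant = c("classic", "bias_corrected")) {
  assert_hygienic(net)
  w <- as_weights(net)
  ab <- w[w > 0L]
  100 * length(ab) / as.numeric(chao1(ab, variant))
}

#' Individual-based rarefaction of a diet
#'
#' Expected taxon richness in a random subsample of n detection events, by
#' the exact hypergeometric formula
#' E\[S_n\] = sum_k (1 - choose(N - N_k, n) / choose(N, n)),
#' where N_k is the number of events recording taxon k and N their total.
#' Evaluated in log space via `lchoose` for stability.
#'
#' @param counts positive integer detection counts per taxon (one bat
#'   species' diet row, zeros allowed and dropped).
#' @param n subsample sizes; default `1:N`.
#' @return an object of class `rarefaction_curve`: data frame with columns
#'   `n` and `expected_richness`, attributes `N` and `S_obs`.
#' @export
rarefy_diet <- function(counts, n = NULL) {
  counts <- counts[counts != 0]
  if (length(counts) < 1L || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers with at least one positive",
         call. = FALSE)
  }
  N <- sum(counts)
  if (is.null(n)) n <- seq_len(N)
  if (any(n < 1) || any(n > N) || any(n != round(n))) {
    stop("subsample sizes must be integers in 1..N", call. = FALSE)
  }
  es <- vapply(n, function(nn) {
    # lchoose(a, b) is -Inf when a < b, making the ratio 0 (taxon certain)
    sum(1 - exp(lchoose(N - counts, nn) - lchoose(N, nn)))
  }, numeric(1))
  structure(data.frame(n = n, expected_richness = es),
            N = N, S_obs = length(counts), class = c("rarefaction_curve",
                                                     "data.frame"))
}

#' Completeness table for a set of networks
#'
#' @param networks named list of hygienic `bipartite_network`s.
#' @param variant Chao1 variant, see [chao1()].
#' @return data frame with per-network links, Chao1 estimate and
#'   completeness percentage.
#' @export
completeness_table <- function(networks, variant = c("classic", "bias_corrected")) {
  variant <- match.arg(variant)
  rows <- lapply(names(networks), function(nm) {
    net <- networks[[nm]]
    w <- as_weights(net)
    ab <- w[w > 0L]
    est <- chao1(ab, variant)
    data.frame(network = nm, links = length(ab),
               chao1 = as.numeric(est),
               chao1_variant = attr(est, "variant"),
               completeness_pct = 100 * length(ab) / as.numeric(est),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
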