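# Core constrained randomizer shared by vaznull_sample() and
# restricted_null_sample(). Fills `L` cells of an nr x nc region one at a
# time with weight 1, sampling empty cells proportional to `p`, restricted at
# each step to cells that keep full coverage of `must_rows` / `must_cols`
# feasible within the remaining cell budget (one cell can cover an uncovered
# row and an uncovered column at once, so the binding constraint is
# max(uncovered rows, uncovered cols) <= remaining cells). The T - L
# remaining interaction events are then dropped on the filled cells
# proportional to `p` renormalized over them.
fill_region <- function(p, L, Tw, must_rows, must_cols, max_tries = 1000L) {
  nr <- nrow(p); nc <- ncol(p)
  stopifnot(L >= 1L, Tw >= L)
  for (try in seq_len(max_tries)) {
    w <- matrix(0L, nr, nc)
    row_cov <- !must_rows          # TRUE once covered (or never required)
    col_cov <- !must_cols
    empty <- !logical(nr * nc)
    ok <- TRUE
    for (placed in seq_len(L)) {
      rem_after <- L - placed      # cells still available after this one
      need_row <- sum(!row_cov) > rem_after
      need_col <- sum(!col_cov) > rem_after
      if (sum(!row_cov) > rem_after + 1L || sum(!col_cov) > rem_after + 1L) {
        ok <- FALSE; break          # dead end even with a double-covering cell
      }
      allowed <- empty
      if (need_row) allowed <- allowed & rep(!row_cov, times = nc)
      if (need_col) allowed <- allowed & rep(!col_cov, each = nr)
      idx <- which(allowed & p > 0)
      if (!length(idx)) idx <- which(allowed)   # p mass zero: fall back uniform
      if (!length(idx)) { ok <- FALSE; break }
      cell <- if (length(idx) == 1L) idx else
        sample(idx, 1L, prob = p[idx] + (all(p[idx] == 0)))
      w[cell] <- 1L
      empty[cell] <- FALSE
      row_cov[(cell - 1L) %% nr + 1L] <- TRUE
      col_cov[(cell - 1L) %/% nr + 1L] <- TRUE
    }
    if (ok && all(row_cov) && all(col_cov)) {
      filled <- which(w > 0L)
      extra <- Tw - L
      if (extra > 0L) {
        pf <- p[filled]
        if (all(pf == 0)) pf <- rep(1, length(pf))
        ev <- sample(seq_along(filled), extra, replace = TRUE, prob = pf)
        w[filled] <- w[filled] + tabulate(ev, nbins = length(filled))
      }
      return(w)
    }
  }
  stop("null-model generation failed after ", max_tries, " attempts",
       call. = FALSE)
}

#' Draw one vaznull randomized matrix
#'
#' The Vazquez et al. (2007) null model: the randomized matrix keeps the
#' observed dimensions, number of links L, and total number of interaction
#' events T, with every species keeping at least one link; cells are chosen
#' with probability proportional to the product of the observed marginal
#' totals, so marginal sums are conserved probabilistically rather than
#' exactly.
#'
#' @param net a hygienic `bipartite_network`.
#' @param max_tries restart budget for the constructive fill.
#' @return a `bipartite_network` with the randomized weights (same labels,
#'   `meta$null_model = "vaznull"`). Uses the current RNG stream; seed control
#'   belongs to [null_distribution()].
#' @export
vaznull_sample <- function(net, max_tries = 1000L) {
  assert_hygienic(net)
  w <- as_weights(net)
  p <- outer(rowSums(w), colSums(w))
  p <- p / sum(p)
  out <- fill_region(p, L = sum(w > 0L), Tw = sum(w),
                     must_rows = rep(TRUE, nrow(w)),
                     must_cols = rep(TRUE, ncol(w)),
                     max_tries = max_tries)
  dimnames(out) <- dimnames(w)
  bipartite_network(out, meta = list(null_model = "vaznull"))
}

#' Draw one module-conserving randomized matrix
#'
#' Extension of the vaznull model that additionally conserves the observed
#' modular structure: the matrix is split into regions by module pair, and
#' the vaznull procedure is applied independently inside every region that
#' holds at least one observed link, preserving the region's link count and
#' weight. Within-module (diagonal) regions also require every member row and
#' column that had an observed within-module link to keep at least one;
#' between-module regions are randomized without a coverage requirement
#' (a species need not keep a between-module link) unless `strict = TRUE`.
#' Regions with no observed links stay empty, so global L and T are conserved
#' by construction.
#'
#' @param net a hygienic `bipartite_network`.
#' @param partition a `module_partition` for `net` (normally the observed
#'   best partition).
#' @param strict also require coverage inside between-module regions.
#' @param max_tries restart budget per region.
#' @return a `bipartite_network` (`meta$null_model = "restricted"`).
#' @export
restricted_null_sample <- function(net, partition, strict = FALSE,
                                   max_tries = 1000L) {
  assert_hygienic(net)
  w <- as_weights(net)
  g <- partition$row_modules
  h <- partition$col_modules
  if (length(g) != nrow(w) || length(h) != ncol(w)) {
    stop("partition does not match network dimensions", call. = FALSE)
  }
  p_full <- outer(rowSums(w), colSums(w))
  out <- matrix(0L, nrow(w), ncol(w), dimnames = dimnames(w))
  for (a in sort(unique(g))) {
    for (b in sort(unique(h))) {
      ri <- which(g == a); ci <- which(h == b)
      sub <- w[ri, ci, drop = FALSE]
      Lr <- sum(sub > 0L)
      if (Lr == 0L) next
      diagonal <- identical(a, b)
      mr <- if (diagonal || strict) rowSums(sub) > 0 else rep(FALSE, length(ri))
      mc <- if (diagonal || strict) colSums(sub) > 0 else rep(FALSE, length(ci))
      out[ri, ci] <- fill_region(p_full[ri, ci, drop = FALSE], L = Lr,
                                 Tw = sum(sub), must_rows = mr, must_cols = mc,
                                 max_tries = max_tries)
    }
  }
  bipartite_network(out, meta = list(null_model = "restricted"))
}

#' z-score of an observed value against a null distribution
#'
#' (observed - mean(null)) / sd(null), with the n-1 sample standard
#' deviation. `NA` when the null values are constant (sd = 0).
#'
#' @param observed the observed metric value.
#' @param null_values numeric vector of length >= 2.
#' @return a number, or `NA` if the null spread is zero.
#' @export
z_score <- function(observed, null_values) {
  if (length(null_values) < 2L) stop("need at least 2 null values", call. = FALSE)
  s <- stats::sd(null_values)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (observed - mean(null_values)) / s
}

# Built-in metric evaluators for null_distribution(). Each takes (net,
# partition, reps): `partition` is the observed partition (used only where
# modules are held fixed), `reps` the module-search restarts.
null_metric_fun <- function(metric, refit_modules) {
  switch(metric,
    connectance = function(net, partition, reps) connectance(net),
    wnodf = function(net, partition, reps) wnodf(net),
    total = function(net, partition, reps) total_weight(net),
    links = function(net, partition, reps) n_links(net),
    modularity = function(net, partition, reps)
      find_modules(net, reps = reps, seed = NULL)$Q,
    wnodf_sm = function(net, partition, reps) {
      part <- if (refit_modules) find_modules(net, reps = reps, seed = NULL)
              else partition
      wnodf_sm(net, part)
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Null distribution and z-score of a network metric
#'
#' Draws `n` randomized matrices from the chosen null model, evaluates the
#' metric on each with the same configuration as on the observed network, and
#' returns the ensemble with its z-score. Under the module-conserving
#' (`"restricted"`) model, `wnodf_sm` is evaluated at the observed partition
#' (which the null conserves); under `"vaznull"` modules are re-detected on
#' every replicate.
#'
#' @param net a hygienic `bipartite_network`.
#' @param metric one of `"wnodf"`, `"modularity"`, `"wnodf_sm"`,
#'   `"connectance"`, `"total"`, `"links"`.
#' @param model `"vaznull"` or `"restricted"`.
#' @param n number of null replicates (the study default is 1000).
#' @param seed integer seed for the whole ensemble; same seed, same ensemble.
#' @param partition observed module partition; computed with [find_modules()]
#'   when needed and not supplied.
#' @param reps module-search restarts used for the observed value and for
#'   replicates that re-detect modules.
#' @param max_failure_rate abort when more than this fraction of replicates
#'   fail to generate.
#' @param strict passed to [restricted_null_sample()].
#' @return an object of class `null_ensemble`: list with `metric`, `model`,
#'   `observed`, `null_values`, `z`, `n`, `n_failures`, `seed`.
#' @export
null_distribution <- function(net, metric, model = c("vaznull", "restricted"),
                              n = 1000L, seed = NULL, partition = NULL,
                              reps = 10L, max_failure_rate = 0.1,
                              strict = FALSE) {
  model <- match.arg(model)
  assert_hygienic(net)
  if (n < 2L) stop("need n >= 2 null replicates", call. = FALSE)
  with_seed(seed, {
    if (is.null(partition) && (model == "restricted" ||
                               metric %in% c("modularity", "wnodf_sm"))) {
      partition <- find_modules(net, reps = reps, seed = NULL)
    }
    fun <- null_metric_fun(metric, refit_modules = (model == "vaznull"))
    observed <- if (metric == "modularity" && !is.null(partition)) partition$Q
                else fun(net, partition, reps)
    null_values <- numeric(n)
    failures <- 0L
    max_fail <- ceiling(max_failure_rate * n)
    i <- 0L
    while (i < n) {
      rnet <- tryCatch(
        if (model == "vaznull") vaznull_sample(net)
        else restricted_null_sample(net, partition, strict = strict),
        error = function(e) NULL)
      if (is.null(rnet)) {
        failures <- failures + 1L
        if (failures > max_fail) {
          stop(sprintf("null generation failure budget exceeded (%d of %d)",
                       failures, n), call. = FALSE)
        }
        next
      }
      i <- i + 1L
      null_values[i] <- fun(rnet, partition, reps)
    }
    structure(list(metric = metric, model = model, observed = observed,
                   null_values = null_values,
                   z = z_score(observed, null_values),
                   n = n, n_failures = failures, seed = seed),
              class = "null_ensemble")
  })
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s vs %s: observed %.4f, null %.4f +/- %.4f, z = %s (n = %d, %d failures)\n",
              x$metric, x$model, x$observed, mean(x$null_values),
              stats::sd(x$null_values),
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)),
              x$n, x$n_failures))
  invisible(x)
}
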