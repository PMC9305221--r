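#' Full structural report for one network
#'
#' Computes the five structure descriptors (plant/bat richness implicit in
#' the dimensions, number of compartments, WNODF, Barber modularity via
#' DIRTLPAwb+, within-module WNODF, connectance) and, when `nulls > 0`,
#' z-scores against the null models: WNODF and modularity against vaznull,
#' within-module WNODF against the module-conserving null.
#'
#' @param net a hygienic `bipartite_network`.
#' @param nulls number of null replicates per metric (0 = no z-scores; the
#'   study convention is 1000).
#' @param reps DIRTLPAwb+ restarts per initial module count.
#' @param seed integer seed; expanded internally into independent sub-seeds
#'   for module search and each null ensemble.
#' @param chao_variant Chao1 variant for the completeness entry.
#' @return an object of class `structure_report`: a list with the metric
#'   values, `z` (named list of z-scores or NULL), `partition`, and the
#'   configuration used.
#' @export
structure_report <- function(net, nulls = 1000L, reps = 10L, seed = NULL,
                             chao_variant = c("classic", "bias_corrected")) {
  chao_variant <- match.arg(chao_variant)
  assert_hygienic(net)
  part <- find_modules(net, reps = reps, seed = derive_seed(seed, 1L))
  rep_out <- list(
    meta = if (inherits(net, "bipartite_network")) net$meta else list(),
    plant_richness = n_cols(net),
    bat_richness = n_rows(net),
    n_compartments = compartments(net)$n,
    wnodf = wnodf(net),
    modularity = part$Q,
    wnodf_sm = wnodf_sm(net, part),
    connectance = connectance(net),
    total_weight = total_weight(net),
    n_links = n_links(net),
    completeness_pct = network_completeness(net, chao_variant),
    z = NULL,
    partition = part,
    config = list(nulls = nulls, reps = reps, seed = seed,
                  chao_variant = chao_variant)
  )
  if (nulls > 0L) {
    z_wnodf <- null_distribution(net, "wnodf", "vaznull", n = nulls,
                                 seed = derive_seed(seed, 2L),
                                 partition = part, reps = reps)
    z_mod <- null_distribution(net, "modularity", "vaznull", n = nulls,
                               seed = derive_seed(seed, 3L),
                               partition = part, reps = reps)
    z_sm <- null_distribution(net, "wnodf_sm", "restricted", n = nulls,
                              seed = derive_seed(seed, 4L),
                              partition = part, reps = reps)
    rep_out$z <- list(wnodf = z_wnodf$z, modularity = z_mod$z,
                      wnodf_sm = z_sm$z)
  }
  structure(rep_out, class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  zs <- function(m) {
    if (is.null(x$z) || is.na(x$z[[m]])) "" else sprintf(" (z = %.1f)", x$z[[m]])
  }
  cat("<structure_report>\n")
  cat(sprintf("  plant richness %d, bat richness %d, compartments %d\n",
              x$plant_richness, x$bat_richness, x$n_compartments))
  cat(sprintf("  WNODF        %.2f%s\n", x$wnodf, zs("wnodf")))
  cat(sprintf("  modularity   %.2f%s\n", x$modularity, zs("modularity")))
  cat(sprintf("  WNODF_SM     %.2f%s\n", x$wnodf_sm, zs("wnodf_sm")))
  cat(sprintf("  connectance  %.2f, completeness %.2f%%\n",
              x$connectance, x$completeness_pct))
  invisible(x)
}

#' One-row data frame view of a structure report
#'
#' Columns follow the study-table order: richnesses, compartments, WNODF,
#' modularity, within-module WNODF, connectance, then z-scores.
#'
#' @param x a `structure_report`.
#' @param ... unused.
#' @export
as.data.frame.structure_report <- function(x, ...) {
  data.frame(
    plant_richness = x$plant_richness,
    bat_richness = x$bat_richness,
    n_compartments = x$n_compartments,
    wnodf = x$wnodf,
    modularity = x$modularity,
    wnodf_sm = x$wnodf_sm,
    connectance = x$connectance,
    completeness_pct = x$completeness_pct,
    z_wnodf = if (is.null(x$z)) NA_real_ else x$z$wnodf,
    z_modularity = if (is.null(x$z)) NA_real_ else x$z$modularity,
    z_wnodf_sm = if (is.null(x$z)) NA_real_ else x$z$wnodf_sm
  )
}

#' Serialize / parse a structure report as JSON
#'
#' The partition is stored as named module-id vectors; all numeric fields
#' round-trip exactly (no rounding applied).
#'
#' @param x a `structure_report`.
#' @return `report_to_json`: a JSON string; `report_from_json`: a list with
#'   the same fields as the report.
#' @export
report_to_json <- function(x) {
  out <- unclass(x)
  out$partition <- list(row_modules = as.list(x$partition$row_modules),
                        col_modules = as.list(x$partition$col_modules),
                        Q = x$partition$Q)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname report_to_json
#' @param json a JSON string produced by `report_to_json`.
#' @export
report_from_json <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE)
}

#' Analyze a batch of networks
#'
#' Runs [structure_report()] on every network with per-network sub-seeds
#' derived from one global seed (adding a network to the batch does not
#' change the others' results).
#'
#' @param networks named list of hygienic `bipartite_network`s.
#' @param nulls,reps,seed,chao_variant passed to [structure_report()].
#' @return list with `reports` (named list of `structure_report`s) and
#'   `table` (combined data frame, one row per network).
#' @export
analyze_networks <- function(networks, nulls = 1000L, reps = 10L, seed = NULL,
                             chao_variant = "classic") {
  if (is.null(names(networks)) || anyDuplicated(names(networks))) {
    stop("networks must be uniquely named", call. = FALSE)
  }
  reports <- lapply(seq_along(networks), function(i) {
    structure_report(networks[[i]], nulls = nulls, reps = reps,
                     seed = derive_seed(seed, 100L * i),
                     chao_variant = chao_variant)
  })
  names(reports) <- names(networks)
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  tab <- cbind(network = names(networks), tab, row.names = NULL)
  list(reports = reports, table = tab)
}

#' Re-run the study pipeline on deposited interaction matrices
#'
#' Reads every `*.csv` interaction matrix found in `data_dir` (the layout of
#' [read_network_csv()]), applies hygiene, and produces the full pipeline
#' output: per-network structure reports with z-scores, the pairwise
#' beta-diversity table, and the sampling-completeness table. Intended for
#' the deposited matrices of the source field study ("Molecular food webs of
#' bat-plant interactions", DRYAD doi:10.5061/dryad.0rxwdbs29), which are
#' not redistributed with this package.
#'
#' @param data_dir directory holding the matrix CSV files.
#' @param nulls,reps,seed passed to [analyze_networks()].
#' @param transpose set `TRUE` if the files store plants as rows.
#' @return list with `networks`, `analysis` (see [analyze_networks()]),
#'   `beta` (see [beta_table()]), `completeness` (see
#'   [completeness_table()]).
#' @export
reproduce_study <- function(data_dir, nulls = 1000L, reps = 10L, seed = 1L,
                            transpose = FALSE) {
  if (!dir.exists(data_dir)) {
    stop("data directory not found: ", data_dir,
         "\nPlace the deposited interaction-matrix CSVs there to reproduce ",
         "the study tables.", call. = FALSE)
  }
  files <- list.files(data_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no .csv matrices in ", data_dir, call. = FALSE)
  nets <- lapply(files, function(f) {
    drop_empty(read_network_csv(f, transpose = transpose))
  })
  names(nets) <- sub("\\.csv$", "", basename(files))
  analysis <- analyze_networks(nets, nulls = nulls, reps = reps, seed = seed)
  list(networks = nets,
       analysis = analysis,
       beta = beta_table(nets),
       completeness = completeness_table(nets))
}
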