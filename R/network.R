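#' Construct a weighted bipartite interaction network
#'
#' The central container of the package: a labelled matrix of nonnegative
#' integer interaction counts between a consumer guild (rows, by convention
#' bats) and a resource guild (columns, by convention plants). A cell value is
#' the number of individual consumers in whose faeces the resource taxon was
#' detected, i.e. the number of realised interaction events.
#'
#' @param weights numeric matrix of nonnegative integer-valued counts. Row and
#'   column names, if absent, are taken from `row_labels` / `col_labels`.
#' @param row_labels,col_labels optional character vectors of unique taxon
#'   names; default to the matrix dimnames or `bat1..R` / `plant1..C`.
#' @param meta named list of free-form provenance tags (site, season, year,
#'   source path, ...).
#' @param int_tol tolerance within which a decimal cell (e.g. `3.0000001`) is
#'   accepted as the integer it rounds to.
#' @return an object of class `bipartite_network` with elements `weights`
#'   (integer matrix with dimnames) and `meta`.
#' @examples
#' net <- bipartite_network(matrix(c(2, 1, 0, 1), 2, 2))
#' total_weight(net)
#' @export
bipartite_network <- function(weights, row_labels = NULL, col_labels = NULL,
                              meta = list(), int_tol = 1e-6) {
  if (!is.matrix(weights)) weights <- as.matrix(weights)
  if (nrow(weights) < 1L || ncol(weights) < 1L) {
    stop("a bipartite network needs at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(weights)) stop("weights must be numeric", call. = FALSE)
  if (anyNA(weights)) stop("weights contain NA", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  rw <- round(weights)
  if (any(abs(weights - rw) > int_tol)) {
    bad <- which(abs(weights - rw) > int_tol, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer weight at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (is.null(row_labels)) {
    row_labels <- rownames(weights)
    if (is.null(row_labels)) row_labels <- paste0("bat", seq_len(nrow(weights)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(weights)
    if (is.null(col_labels)) col_labels <- paste0("plant", seq_len(ncol(weights)))
  }
  row_labels <- trimws(as.character(row_labels))
  col_labels <- trimws(as.character(col_labels))
  if (length(row_labels) != nrow(weights) || length(col_labels) != ncol(weights)) {
    stop("label length does not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(row_labels)) {
    stop("duplicate row (bat) label: ",
         paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(col_labels)) {
    stop("duplicate column (plant) label: ",
         paste(unique(col_labels[duplicated(col_labels)]), collapse = ", "),
         call. = FALSE)
  }
  w <- matrix(as.integer(rw), nrow(weights), ncol(weights),
              dimnames = list(row_labels, col_labels))
  structure(list(weights = w, meta = meta), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d bats x %d plants, L = %d links, T = %d events\n",
              nrow(x$weights), ncol(x$weights), n_links(x), total_weight(x)))
  if (length(x$meta)) {
    tags <- vapply(x$meta, function(v) paste(format(v), collapse = ","), character(1))
    cat("  meta: ", paste(names(tags), tags, sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Basic size descriptors of a network
#'
#' `total_weight` is the total number of interaction events (the sum of all
#' cells, written T); `n_links` the number of realised links (nonzero cells,
#' L); `n_rows`/`n_cols` the guild richnesses R and C.
#' @param net a `bipartite_network`.
#' @return a single integer.
#' @export
total_weight <- function(net) sum(as_weights(net))

#' @rdname total_weight
#' @export
n_links <- function(net) sum(as_weights(net) > 0L)

#' @rdname total_weight
#' @export
n_rows <- function(net) nrow(as_weights(net))

#' @rdname total_weight
#' @export
n_cols <- function(net) ncol(as_weights(net))

# Accepts a network or a bare matrix; all metric code funnels through here.
as_weights <- function(net) {
  if (inherits(net, "bipartite_network")) return(net$weights)
  if (is.matrix(net) && is.numeric(net)) return(net)
  stop("expected a bipartite_network or a numeric matrix", call. = FALSE)
}

#' Remove species with no interactions
#'
#' Drops every row and column whose marginal total is zero. Downstream metrics
#' (connectance, nestedness, modularity) are defined on interacting species
#' only, so this is the standard hygiene step after subsetting a matrix by
#' season or site. Survivor order is preserved; removed labels are recorded in
#' `meta$dropped_rows` / `meta$dropped_cols`.
#'
#' @param net a `bipartite_network`.
#' @return a `bipartite_network` in which every row and column sum is positive.
#' @export
drop_empty <- function(net) {
  w <- as_weights(net)
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  if (!any(keep_r) || !any(keep_c)) {
    stop("degenerate network: no interacting species remain", call. = FALSE)
  }
  meta <- if (inherits(net, "bipartite_network")) net$meta else list()
  if (!all(keep_r)) meta$dropped_rows <- union(meta$dropped_rows, rownames(w)[!keep_r])
  if (!all(keep_c)) meta$dropped_cols <- union(meta$dropped_cols, colnames(w)[!keep_c])
  bipartite_network(w[keep_r, keep_c, drop = FALSE], meta = meta)
}

# Errors unless the network is hygienic (all margins positive).
assert_hygienic <- function(net) {
  w <- as_weights(net)
  if (any(rowSums(w) == 0) || any(colSums(w) == 0)) {
    stop("network has empty rows or columns; call drop_empty() first", call. = FALSE)
  }
  invisible(net)
}

#' Read an interaction matrix from CSV
#'
#' Expects the layout produced by `write.csv` on a labelled matrix: the header
#' row holds plant labels (its first cell may be blank or an id column name),
#' the first column holds bat labels, and the body holds nonnegative integer
#' counts. Decimal cells within `int_tol` of an integer are accepted, since
#' count matrices round-tripped through other tools often gain a `.0`.
#'
#' @param path path to the CSV file.
#' @param transpose set `TRUE` when the file has plants as rows and bats as
#'   columns; the matrix is transposed after reading (never auto-detected).
#' @param int_tol tolerance for integral-valued decimals.
#' @return a `bipartite_network`; `meta$source` records `path`. No hygiene is
#'   applied: empty rows/columns in the file are kept.
#' @seealso [write_network_csv()], [drop_empty()]
#' @export
read_network_csv <- function(path, transpose = FALSE, int_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, row.names = NULL,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("matrix CSV needs a label column plus data: ", path,
                          call. = FALSE)
  labs <- trimws(as.character(df[[1L]]))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2)) {
        i <- which(is.na(v2))[1L]
        stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                     v[i], labs[i], names(body)[j], path), call. = FALSE)
      }
      body[[j]] <- v2
    }
  }
  m <- as.matrix(body)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row '%s', column '%s' in %s",
                 labs[bad[1L]], colnames(m)[bad[2L]], path), call. = FALSE)
  }
  if (any(abs(m - round(m)) > int_tol)) {
    bad <- which(abs(m - round(m)) > int_tol, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integral count at row '%s', column '%s' in %s",
                 labs[bad[1L]], colnames(m)[bad[2L]], path), call. = FALSE)
  }
  rownames(m) <- labs
  if (transpose) m <- t(m)
  bipartite_network(m, meta = list(source = path), int_tol = int_tol)
}

#' Write an interaction matrix to CSV
#'
#' Inverse of [read_network_csv()]: header = plant labels with a blank first
#' cell, first column = bat labels, integer counts.
#'
#' @param net a `bipartite_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  w <- as_weights(net)
  if (nrow(w) == 0L || ncol(w) == 0L) stop("refusing to write an empty network",
                                           call. = FALSE)
  utils::write.csv(as.data.frame(w, check.names = FALSE), path,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert between matrix and edge-list representations
#'
#' `as_edge_list` returns one record per realised link (zero cells omitted);
#' `edge_list_to_network` rebuilds the matrix, so the round trip equals
#' `drop_empty(net)`. The TSV dialect used by [read_edge_list_tsv()] has the
#' header `bat<TAB>plant<TAB>count`.
#'
#' @param net a `bipartite_network`.
#' @return `as_edge_list`: a data frame with columns `bat`, `plant`, `count`.
#' @export
as_edge_list <- function(net) {
  w <- as_weights(net)
  idx <- which(w > 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(bat = rownames(w)[idx[, 1L]],
             plant = colnames(w)[idx[, 2L]],
             count = w[idx],
             stringsAsFactors = FALSE)
}

#' @rdname as_edge_list
#' @param edges data frame with columns `bat`, `plant`, `count` (positive
#'   integers, no duplicate pairs).
#' @param meta provenance tags for the new network.
#' @export
edge_list_to_network <- function(edges, meta = list()) {
  need <- c("bat", "plant", "count")
  if (!all(need %in% names(edges))) {
    stop("edge list needs columns bat, plant, count", call. = FALSE)
  }
  if (nrow(edges) == 0L) stop("empty edge list", call. = FALSE)
  if (any(edges$count < 1)) stop("edge counts must be >= 1", call. = FALSE)
  key <- paste(edges$bat, edges$plant, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (bat, plant) pair in edge list: ",
         sub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
  }
  bats <- unique(trimws(as.character(edges$bat)))
  plants <- unique(trimws(as.character(edges$plant)))
  w <- matrix(0L, length(bats), length(plants), dimnames = list(bats, plants))
  w[cbind(match(trimws(edges$bat), bats), match(trimws(edges$plant), plants))] <-
    as.integer(round(edges$count))
  bipartite_network(w, meta = meta)
}

#' @rdname as_edge_list
#' @param path path of a TSV edge-list file.
#' @export
read_edge_list_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  edge_list_to_network(df, meta = list(source = path))
}

#' @rdname as_edge_list
#' @export
write_edge_list_tsv <- function(net, path) {
  utils::write.table(as_edge_list(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
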