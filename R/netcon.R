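#' Fisher-z connectivity matrix from ROI time series
#'
#' Pearson correlation between every pair of node signals over the valid
#' frames, Fisher-transformed (z = atanh(r)) to improve normality.
#' Correlations with |r| = 1 (e.g. duplicated nodes) are clipped to
#' 1 - 1e-7 before the transform so z stays finite. Diagonal is 0.
#'
#' @param ts a [roi_timeseries()].
#' @param node_labels optional node names.
#' @return nodes x nodes symmetric matrix of class `connectivity_matrix`
#'   with attribute `node_labels`.
#' @export
correlation_matrix <- function(ts, node_labels = NULL) {
  X <- ts$data[ts$valid_mask, , drop = FALSE]
  stop_if_not(nrow(X) >= 3L, "need at least 3 valid frames, have %d", nrow(X))
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0)) {
    stop(sprintf("zero-variance node(s): %s",
                 paste(which(v <= 0), collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(X)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            node_labels = node_labels %||% colnames(ts$data))
}

#' The proportional-threshold grid
#' @param from,to,by grid limits and step (fractions of possible edges).
#' @return numeric vector, strictly increasing within (0, 1).
#' @export
sparsity_grid <- function(from = 0.10, to = 0.30, by = 0.01) {
  g <- seq(from, to, by)
  stop_if_not(all(g > 0 & g < 1), "sparsity values must lie in (0,1)")
  stop_if_not(all(diff(g) > 0), "sparsity grid must be strictly increasing")
  g
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Keeps the E = round(sparsity * N(N-1)/2) largest off-diagonal values
#' as edges (round half away from zero). Selection is on signed values:
#' strong negative correlations are not selected. Ties at the cut are
#' broken by ascending (i, j) lexicographic node index, making the edge
#' set at a lower sparsity always a subset of the edge set at a higher
#' one.
#'
#' @param cm symmetric matrix of connection weights (Fisher z).
#' @param sparsity fraction of possible edges to keep, in (0, 1).
#' @return object of class `binary_graph`: list with `adjacency`
#'   (0/1 symmetric matrix) and `sparsity`.
#' @export
binarize <- function(cm, sparsity) {
  stop_if_not(sparsity > 0 && sparsity < 1, "sparsity must be in (0,1)")
  n <- nrow(cm)
  emax <- n * (n - 1) / 2
  E <- round_half_up(sparsity * emax)
  stop_if_not(E >= 1, "sparsity %.3g keeps zero edges on %d nodes",
              sparsity, n)
  up <- upper_pairs(n)
  w <- cm[up]
  ord <- order(-w, up[, 1L], up[, 2L])
  keep <- ord[seq_len(E)]
  A <- matrix(0L, n, n)
  A[up[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(unclass(cm))
  binary_graph(A, sparsity = sparsity)
}

#' Construct a binary graph object
#' @param adjacency 0/1 symmetric matrix, zero diagonal.
#' @param sparsity fraction of possible edges present (computed if NULL).
#' @return object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, sparsity = NULL) {
  stop_if_not(isTRUE(all.equal(adjacency, t(adjacency))),
              "adjacency must be symmetric")
  stop_if_not(all(diag(adjacency) == 0), "self-loops are not allowed")
  stop_if_not(all(adjacency %in% c(0L, 1L)), "adjacency must be 0/1")
  n <- nrow(adjacency)
  structure(list(adjacency = adjacency,
                 sparsity = sparsity %||% (sum(adjacency) / (n * (n - 1)))),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("binary graph: %d nodes, %d edges (sparsity %.3f)\n",
              n, sum(x$adjacency) / 2, x$sparsity))
  invisible(x)
}

as_adjacency <- function(g) {
  if (inherits(g, "binary_graph")) g$adjacency else g
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(as_adjacency(g), mode = "undirected")
}

#' Group-averaged occurrence graph
#'
#' An edge enters the group graph iff it is present in at least
#' ceiling(tau * n_subjects) of the individual binarized graphs. The
#' result is monotone decreasing in `tau`; `tau = 1` is the intersection
#' of all graphs.
#'
#' @param graphs list of `binary_graph` over the same node set.
#' @param tau occurrence fraction in (0, 1].
#' @return a `binary_graph`.
#' @export
group_occurrence_graph <- function(graphs, tau) {
  stop_if_not(length(graphs) >= 1L, "empty graph list")
  stop_if_not(tau > 0 && tau <= 1, "tau must be in (0, 1]")
  mats <- lapply(graphs, as_adjacency)
  n <- nrow(mats[[1L]])
  stop_if_not(all(vapply(mats, nrow, 0L) == n), "graphs differ in node count")
  counts <- Reduce(`+`, mats)
  need <- ceiling(tau * length(graphs) - 1e-9)
  A <- 1L * (counts >= need)
  binary_graph(A)
}

#' Write a connectivity matrix as an edge list (i, j, z)
#' @param cm connectivity matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(cm, path) {
  n <- nrow(cm)
  up <- upper_pairs(n)
  df <- data.frame(i = up[, 1L], j = up[, 2L], z = round(cm[up], 6L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
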