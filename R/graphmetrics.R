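## Global/nodal topology of binary graphs, degree-preserving null
## normalization, and AUC integration over the threshold grid.
## Conventions (GRETNA-compatible): the clustering coefficient averages
## 2*triangles/(k(k-1)) over all nodes with 0 for degree < 2; the
## characteristic path length is the mean shortest path over connected
## pairs of the largest connected component; efficiencies use 1/Inf = 0
## globally so disconnection is handled natively.

cp_of <- function(ig) {
  mean(igraph::transitivity(ig, type = "localundirected", isolates = "zero"))
}

lp_of <- function(ig) {
  if (igraph::is_connected(ig)) {
    return(igraph::mean_distance(ig, directed = FALSE, unconnected = FALSE))
  }
  comp <- igraph::components(ig)
  if (max(comp$csize) < 2L) return(NA_real_)
  main <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(ig, main)
  igraph::mean_distance(sub, directed = FALSE, unconnected = FALSE)
}

eglob_of <- function(ig) {
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

eloc_of <- function(ig, adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2L) next
    sub <- igraph::graph_from_adjacency_matrix(adj[nb, nb, drop = FALSE],
                                               mode = "undirected")
    vals[i] <- eglob_of(sub)
  }
  mean(vals)
}

#' Degree-preserving rewired null graph
#'
#' Randomizes the edge set by repeated double-edge swaps that preserve
#' the degree sequence exactly and reject self-loops and multi-edges.
#'
#' @param g a `binary_graph` (or adjacency matrix).
#' @param n_swaps_per_edge attempted swaps per edge.
#' @param seed optional integer seed.
#' @return a `binary_graph` with the same degree sequence.
#' @export
rewire_null <- function(g, n_swaps_per_edge = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ig <- as_igraph(g)
  m <- igraph::ecount(ig)
  stop_if_not(m >= 2L, "need at least 2 edges to rewire")
  rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_swaps_per_edge * m))
  A <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  storage.mode(A) <- "integer"
  dimnames(A) <- dimnames(as_adjacency(g))
  binary_graph(A)
}

#' Global topological metrics of a binary graph
#'
#' Computes the clustering coefficient (Cp), characteristic path length
#' (Lp), global and local efficiency, and the random-network-normalized
#' quantities gamma = Cp/Cp_rand, lambda = Lp/Lp_rand and small-world-ness
#' sigma = gamma/lambda, where the null values are means over `n_null`
#' degree-preserving rewired graphs.
#'
#' The null ensemble is sampled along one double-edge-swap Markov chain:
#' `null_burnin` attempted swaps per edge of burn-in, then one sample
#' every `null_thin` swaps per edge. Every sample has exactly the
#' original degree sequence; thinning keeps consecutive samples nearly
#' independent at a fraction of the cost of restarting the chain.
#'
#' @param g a `binary_graph` (or adjacency matrix).
#' @param n_null number of rewired null graphs (0 skips normalization).
#' @param seed optional integer seed for the null ensemble.
#' @param include_efficiency compute Eglob/Eloc (can be skipped when only
#'   the small-world quantities are needed).
#' @param null_burnin,null_thin attempted swaps per edge before the
#'   first null sample and between consecutive samples.
#' @return named list: cp, lp, gamma, lambda, sigma, e_glob, e_loc,
#'   cp_rand, lp_rand.
#' @export
global_metrics <- function(g, n_null = 100, seed = NULL,
                           include_efficiency = TRUE,
                           null_burnin = 10, null_thin = 1) {
  adj <- as_adjacency(g)
  stop_if_not(sum(adj) > 0, "graph has no edges")
  ig <- as_igraph(adj)
  cp <- cp_of(ig)
  lp <- lp_of(ig)
  e_glob <- if (include_efficiency) eglob_of(ig) else NA_real_
  e_loc <- if (include_efficiency) eloc_of(ig, adj) else NA_real_
  gamma <- lambda <- sigma <- cp_rand <- lp_rand <- NA_real_
  if (n_null > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- igraph::ecount(ig)
    cps <- lps <- numeric(n_null)
    rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = null_burnin * m))
    for (b in seq_len(n_null)) {
      if (b > 1L) {
        rg <- igraph::rewire(rg,
                             igraph::keeping_degseq(niter = null_thin * m))
      }
      cps[b] <- cp_of(rg)
      lps[b] <- lp_of(rg)
    }
    cp_rand <- mean(cps)
    lp_rand <- mean(lps)
    gamma <- cp / cp_rand
    lambda <- lp / lp_rand
    sigma <- gamma / lambda
  }
  list(cp = cp, lp = lp, gamma = gamma, lambda = lambda, sigma = sigma,
       e_glob = e_glob, e_loc = e_loc, cp_rand = cp_rand, lp_rand = lp_rand)
}

#' Nodal degree and efficiency
#'
#' Degree is the row sum of the adjacency matrix; nodal efficiency of
#' node i is the mean of 1/d(i, j) over all other nodes j (0 for
#' unreachable pairs, so isolated nodes get efficiency 0).
#'
#' @param g a `binary_graph` (or adjacency matrix).
#' @return list with numeric vectors `degree` and `efficiency`.
#' @export
nodal_metrics <- function(g) {
  adj <- as_adjacency(g)
  ig <- as_igraph(adj)
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  list(degree = rowSums(adj),
       efficiency = rowSums(inv) / (nrow(adj) - 1))
}

#' A metric curve over a threshold grid with its AUC
#' @param grid threshold values (sparsity or occurrence fractions).
#' @param values metric value at each grid point.
#' @return object of class `metric_curve` with fields `grid`, `values`,
#'   `auc` (trapezoidal integral over the literal grid).
#' @export
metric_curve <- function(grid, values) {
  structure(list(grid = grid, values = values, auc = trapz(grid, values)),
            class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("metric curve over %d thresholds [%.3g, %.3g]; AUC = %.6g\n",
              length(x$grid), min(x$grid), max(x$grid), x$auc))
  invisible(x)
}

#' Global metric curves for one subject over the sparsity grid
#'
#' Binarizes the subject's connectivity matrix at every grid value and
#' computes the global metrics, returning one [metric_curve()] per
#' metric (including its AUC).
#'
#' @param cm `connectivity_matrix` (Fisher z).
#' @param grid sparsity grid, see [sparsity_grid()].
#' @param n_null rewired null graphs per threshold.
#' @param seed optional seed.
#' @param include_efficiency see [global_metrics()].
#' @return named list of `metric_curve` objects
#'   (cp, lp, gamma, lambda, sigma, e_glob, e_loc).
#' @export
global_metric_curves <- function(cm, grid = sparsity_grid(), n_null = 100,
                                 seed = NULL, include_efficiency = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(grid, function(s)
    global_metrics(binarize(cm, s), n_null = n_null,
                   include_efficiency = include_efficiency))
  keep <- c("cp", "lp", "gamma", "lambda", "sigma", "e_glob", "e_loc")
  out <- lapply(stats::setNames(keep, keep), function(m)
    metric_curve(grid, vapply(rows, `[[`, 0, m)))
  out
}

#' Nodal metric curves (degree/efficiency) with AUC per node
#'
#' @param cm `connectivity_matrix`.
#' @param grid sparsity grid.
#' @return list with matrices `degree` and `efficiency`
#'   (thresholds x nodes) and vectors `degree_auc`, `efficiency_auc`.
#' @export
nodal_metric_curves <- function(cm, grid = sparsity_grid()) {
  res <- lapply(grid, function(s) nodal_metrics(binarize(cm, s)))
  deg <- do.call(rbind, lapply(res, `[[`, "degree"))
  eff <- do.call(rbind, lapply(res, `[[`, "efficiency"))
  list(degree = deg, efficiency = eff,
       degree_auc = apply(deg, 2L, function(y) trapz(grid, y)),
       efficiency_auc = apply(eff, 2L, function(y) trapz(grid, y)))
}

#' Group-level small-world curves from a simulated or loaded cohort
#'
#' Cleans each subject's time series (optional), computes Fisher-z
#' connectivity, averages the z matrices within each group, binarizes
#' the group matrix at every sparsity in the grid, and evaluates the
#' small-world quantities with degree-preserving rewired nulls.
#'
#' @param cohort result of [generate_cohort()] (or [read_cohort()]).
#' @param grid sparsity grid.
#' @param n_null rewired nulls per graph.
#' @param clean apply the temporal cleaning pipeline first.
#' @return data frame: group, sparsity, cp, lp, gamma, lambda, sigma.
#' @export
small_world_by_group <- function(cohort, grid = sparsity_grid(),
                                 n_null = 50, clean = TRUE) {
  zs <- lapply(seq_along(cohort$timeseries), function(i) {
    ts <- cohort$timeseries[[i]]
    if (clean) ts <- clean_timeseries(ts, cohort$motion[[i]])$ts
    correlation_matrix(ts)
  })
  out <- list()
  for (g in unique(cohort$subjects$group)) {
    idx <- which(cohort$subjects$group == g)
    zbar <- Reduce(`+`, zs[idx]) / length(idx)
    for (s in grid) {
      m <- global_metrics(binarize(zbar, s), n_null = n_null,
                          include_efficiency = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, sparsity = s, cp = m$cp, lp = m$lp,
        gamma = m$gamma, lambda = m$lambda, sigma = m$sigma)
    }
  }
  do.call(rbind, out)
}
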