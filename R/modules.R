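## Community structure: agglomerative greedy modularity maximization
## (Clauset-Newman-Moore style merging with a deterministic tie-break),
## module-level connectivity metrics, and reference partitions from the
## control group's occurrence graphs.

#' Modularity Q of a partition
#'
#' Q = sum_s (e_ss - a_s^2), where e_ss is the fraction of edges inside
#' module s and a_s the fraction of edge endpoints in s.
#'
#' @param g a `binary_graph` (or adjacency matrix).
#' @param labels integer module assignment per node.
#' @return scalar Q in [-0.5, 1].
#' @export
modularity_q <- function(g, labels) {
  adj <- as_adjacency(g)
  m <- sum(adj) / 2
  stop_if_not(m > 0, "graph has no edges")
  q <- 0
  for (s in unique(labels)) {
    inside <- labels == s
    e_ss <- sum(adj[inside, inside]) / 2 / m
    a_s <- sum(adj[inside, ]) / (2 * m)
    q <- q + e_ss - a_s^2
  }
  q
}

#' Greedy modularity community detection
#'
#' Agglomerative Q-maximization: every node starts as its own community
#' and the pair of communities with the largest modularity gain
#' dQ(s, t) = e_st - 2 a_s a_t is merged repeatedly until no merge has a
#' positive gain. Ties are broken deterministically toward the smallest
#' (community-index) pair. Isolated nodes remain singleton modules.
#' Final modules are relabeled in decreasing size order (ties toward the
#' smaller lowest node index).
#'
#' @param g a `binary_graph` (or adjacency matrix).
#' @return object of class `modular_partition`: list with `labels`
#'   (node -> module), `q` (modularity of the partition on `g`),
#'   `sizes`, `n_modules`, `merge_gains` (gain sequence), and
#'   `source_tau` (NA; filled by [hc_reference_partitions()]).
#' @export
greedy_modularity <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  m <- sum(adj) / 2
  stop_if_not(n > 0, "empty graph")
  stop_if_not(m > 0, "graph has no edges")
  if (any(rowSums(adj) == 0)) {
    message(sprintf("%d isolated node(s) assigned singleton modules",
                    sum(rowSums(adj) == 0)))
  }
  W <- adj / m          # off-diagonal: e_st; diagonal: e_ss (starts at 0)
  diag(W) <- 0
  a <- rowSums(adj) / (2 * m)
  member <- seq_len(n)  # node -> active community slot
  active <- seq_len(n)
  q <- -sum(a^2)
  gains <- numeric(0)
  repeat {
    nc <- length(active)
    if (nc == 1L) break
    D <- W - 2 * outer(a, a)
    D[lower.tri(D, diag = TRUE)] <- -Inf
    mx <- max(D)
    if (mx <= 0) break
    hits <- which(D == mx, arr.ind = TRUE)
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    s <- hit[[1L]]; t <- hit[[2L]]
    est <- W[s, t]; ess <- W[s, s]; ett <- W[t, t]
    newrow <- W[s, ] + W[t, ]
    W[s, ] <- newrow; W[, s] <- newrow
    W[s, s] <- ess + ett + est
    a[s] <- a[s] + a[t]
    W <- W[-t, -t, drop = FALSE]
    a <- a[-t]
    member[member == t] <- s
    member[member > t] <- member[member > t] - 1L
    active <- active[-length(active)]
    q <- q + mx
    gains <- c(gains, mx)
  }
  ## relabel by decreasing size, ties toward the smaller first node
  sizes <- tabulate(member)
  firsts <- vapply(seq_along(sizes), function(s) min(which(member == s)), 0L)
  ord <- order(-sizes, firsts)
  labels <- match(member, ord)
  structure(list(labels = labels, q = q,
                 sizes = as.integer(table(labels)),
                 n_modules = max(labels),
                 merge_gains = gains, source_tau = NA_real_,
                 module_names = NULL),
            class = "modular_partition")
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf("modular partition: %d modules (sizes %s), Q = %.4f\n",
              x$n_modules, paste(x$sizes, collapse = "/"), x$q))
  if (!is.na(x$source_tau)) cat(sprintf("  occurrence threshold tau = %.2f\n",
                                        x$source_tau))
  invisible(x)
}

#' Module-level metrics of one subject graph under a reference partition
#'
#' Per node: within-module degree and within-module efficiency (each
#' normalized to the mean of the node's own module; a Guimera-style
#' z-score variant is available), and the participation coefficient
#' 1 - sum_s (k_is / k_i)^2 (0 for isolated nodes). Per module (pair):
#' intra-module and inter-module connectivity as binary edge density by
#' default, or mean Fisher-z weights when `z` is supplied.
#'
#' @param g subject `binary_graph` (or adjacency matrix).
#' @param partition a `modular_partition` (or integer label vector)
#'   covering the graph's nodes.
#' @param normalization `"ratio"` (value / module mean, the default) or
#'   `"zscore"` ((value - module mean) / module SD).
#' @param z optional Fisher-z matrix; switches intra/inter connectivity
#'   to mean weights.
#' @return list with vectors `within_degree`, `within_efficiency`,
#'   `participation` and the symmetric module-by-module matrix
#'   `module_conn` (diagonal = intra-module, off-diagonal = inter-module
#'   connectivity).
#' @export
modular_metrics <- function(g, partition, normalization = c("ratio", "zscore"),
                            z = NULL) {
  normalization <- match.arg(normalization)
  adj <- as_adjacency(g)
  labels <- if (inherits(partition, "modular_partition"))
    partition$labels else partition
  n <- nrow(adj)
  stop_if_not(length(labels) == n, "partition does not cover the graph")
  k <- rowSums(adj)
  mods <- sort(unique(labels))
  M <- length(mods)

  ## per-node within-module degree and efficiency
  kin <- numeric(n)
  ein <- numeric(n)
  for (s in mods) {
    nodes <- which(labels == s)
    if (length(nodes) == 1L) {
      message(sprintf("module %s has a single node; within metrics set to 0", s))
      next
    }
    sub <- adj[nodes, nodes, drop = FALSE]
    kin[nodes] <- rowSums(sub)
    ein[nodes] <- nodal_metrics(sub)$efficiency
  }
  normalize <- function(x) {
    out <- numeric(n)
    for (s in mods) {
      nodes <- which(labels == s)
      if (length(nodes) == 1L) next
      mu <- mean(x[nodes])
      if (normalization == "ratio") {
        out[nodes] <- if (mu > 0) x[nodes] / mu else 0
      } else {
        sdv <- stats::sd(x[nodes])
        out[nodes] <- if (isTRUE(sdv > 0)) (x[nodes] - mu) / sdv else 0
      }
    }
    out
  }

  ## participation coefficient
  part <- numeric(n)
  kis <- vapply(mods, function(s)
    rowSums(adj[, labels == s, drop = FALSE]), numeric(n))
  pos <- k > 0
  part[pos] <- 1 - rowSums((kis[pos, , drop = FALSE] / k[pos])^2)

  ## module-by-module connectivity
  conn <- matrix(NA_real_, M, M, dimnames = list(mods, mods))
  for (si in seq_len(M)) {
    for (ti in si:M) {
      ns <- which(labels == mods[si]); nt <- which(labels == mods[ti])
      if (si == ti) {
        if (length(ns) < 2L) { conn[si, ti] <- 0; next }
        if (is.null(z)) {
          conn[si, ti] <- sum(adj[ns, ns]) / (length(ns) * (length(ns) - 1))
        } else {
          conn[si, ti] <- mean(z[ns, ns][upper.tri(diag(length(ns)))])
        }
      } else {
        val <- if (is.null(z)) mean(adj[ns, nt]) else mean(z[ns, nt])
        conn[si, ti] <- conn[ti, si] <- val
      }
    }
  }
  list(within_degree = normalize(kin),
       within_efficiency = normalize(ein),
       participation = part,
       module_conn = conn)
}

#' Reference partitions from control-group occurrence graphs
#'
#' For each occurrence threshold tau in the grid, builds the
#' group-occurrence graph of the control subjects' binarized networks
#' and runs [greedy_modularity()]. Thresholds yielding an edgeless graph
#' are skipped with a warning. The reporting partition is the one with
#' maximal Q (ties toward the smaller tau). If an atlas table is given,
#' detected modules are named by their majority atlas module.
#'
#' @param graphs list of control-subject `binary_graph` (all binarized at
#'   a common reference sparsity).
#' @param tau_grid occurrence thresholds (default 0.50..0.70 step 0.01).
#' @param atlas optional data frame with columns `node`, `module`.
#' @return list with `partitions` (one per usable tau) and `best`.
#' @export
hc_reference_partitions <- function(graphs, tau_grid = seq(0.50, 0.70, 0.01),
                                    atlas = NULL) {
  parts <- list()
  for (tau in tau_grid) {
    og <- group_occurrence_graph(graphs, tau)
    if (sum(og$adjacency) == 0) {
      warning(sprintf("tau = %.2f yields an edgeless graph; skipped", tau))
      next
    }
    p <- greedy_modularity(og)
    p$source_tau <- tau
    if (!is.null(atlas)) {
      p$module_names <- vapply(seq_len(p$n_modules), function(s) {
        tab <- table(atlas$module[p$labels == s])
        names(tab)[which.max(tab)]
      }, "")
    }
    parts[[length(parts) + 1L]] <- p
  }
  stop_if_not(length(parts) > 0, "no usable occurrence threshold")
  qs <- vapply(parts, `[[`, 0, "q")
  list(partitions = parts, best = parts[[which.max(qs)]])
}

#' Write a partition as delimited text
#' @param partition a `modular_partition`.
#' @param path output file.
#' @param atlas optional atlas table supplying node labels.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, atlas = NULL) {
  df <- data.frame(node = seq_along(partition$labels),
                   module_id = partition$labels)
  if (!is.null(atlas)) df$node_label <- atlas$label
  if (!is.null(partition$module_names))
    df$module_name <- partition$module_names[partition$labels]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
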