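## Independent brute-force oracles used to validate the graph machinery.
## Deliberately naive: plain-R breadth-first search, explicit triangle
## counts, the degree-product modularity formula, and union-find
## components. These never share code with the package internals.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, 0)
  mean(vals)
}

oracle_components_nodes <- function(A) {
  D <- oracle_distances(A)
  seen <- rep(FALSE, nrow(A))
  comps <- list()
  for (i in seq_len(nrow(A))) {
    if (seen[i]) next
    comp <- which(is.finite(D[i, ]))
    seen[comp] <- TRUE
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

oracle_lp <- function(A) {
  comps <- oracle_components_nodes(A)
  main <- comps[[which.max(vapply(comps, length, 0L))]]
  D <- oracle_distances(A[main, main, drop = FALSE])
  mean(D[upper.tri(D)])
}

oracle_eglob <- function(A) {
  D <- oracle_distances(A)
  inv <- ifelse(is.finite(D), 1 / D, 0)
  diag(inv) <- 0
  n <- nrow(A)
  sum(inv) / (n * (n - 1))
}

oracle_eloc <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(A[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

oracle_nodal_efficiency <- function(A) {
  D <- oracle_distances(A)
  inv <- ifelse(is.finite(D), 1 / D, 0)
  diag(inv) <- 0
  rowSums(inv) / (nrow(A) - 1)
}

## Degree-product modularity: Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m)
## over same-module pairs. Algebraically equal to sum_s (e_ss - a_s^2)
## but computed by a different route.
oracle_q <- function(A, labels) {
  k <- rowSums(A)
  m2 <- sum(k)
  same <- outer(labels, labels, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

## Union-find maximal suprathreshold component (in edges).
oracle_max_component_edges <- function(pairs) {
  if (nrow(pairs) == 0L) return(0L)
  nodes <- sort(unique(c(pairs)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (e in seq_len(nrow(pairs))) {
    a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
    if (a != b) parent[[as.character(a)]] <- b
  }
  roots <- vapply(pairs[, 1L], find, 0)
  max(table(roots))
}

oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

## Small random graph with at least one edge.
random_graph <- function(n, p) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    if (sum(A) > 0) return(A)
  }
}

## Reduced cohort specification used where full scale is not needed.
small_spec <- function(...) {
  cohort_spec(group_sizes = c(HC = 8L, FCNAD = 8L, FCAD = 8L),
              n_nodes = 42L, module_sizes = c(9L, 9L, 8L, 4L, 4L, 4L, 4L),
              n_frames = 120L, n_spikes = 2L, ...)
}

oracle_trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}
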