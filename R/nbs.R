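## Network-based statistic: edgewise omnibus F tests over Fisher-z
## connectivity, suprathreshold component extraction, and a permutation
## null of the maximal component size (in edges).

## Flatten a list of symmetric z matrices to subjects x edges.
flatten_z <- function(z_list) {
  n <- nrow(z_list[[1L]])
  up <- upper_pairs(n)
  X <- t(vapply(z_list, function(z) z[up], numeric(nrow(up))))
  list(X = X, pairs = up, n_nodes = n)
}

## Vectorized one-way ANOVA F for every column of X.
## gsum: G x E matrix of group sums; nvec: group sizes.
f_from_sums <- function(gsum, nvec, colsum, colsq, n) {
  ssb <- colSums(gsum^2 / nvec) - colsum^2 / n
  sst <- colsq - colsum^2 / n
  ssw <- sst - ssb
  G <- length(nvec)
  fstat <- (ssb / (G - 1)) / (ssw / (n - G))
  fstat[ssw <= 0] <- Inf
  fstat
}

## Edge count of the largest connected component formed by the given
## edges; 0 when no edges. Returns all components when sizes = TRUE.
edge_components <- function(pairs, sizes = FALSE) {
  if (nrow(pairs) == 0L) {
    return(if (sizes) list() else 0L)
  }
  el <- cbind(as.character(pairs[, 1L]), as.character(pairs[, 2L]))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(ig)$membership
  ecomp <- memb[el[, 1L]]
  tab <- table(ecomp)
  if (!sizes) return(max(tab))
  lapply(names(tab), function(cid) pairs[ecomp == cid, , drop = FALSE])
}

## Residualize columns of X on [1, age, gender].
residualize_edges <- function(X, age, gender) {
  Z <- cbind(1, age, as.numeric(factor(gender)) - 1)
  qr.resid(qr(Z), X)
}

#' Network-based statistic with an omnibus F threshold
#'
#' Per edge, a one-way ANOVA F statistic across the groups is computed on
#' Fisher-z connectivity values (optionally residualized on age and
#' gender first). Edges with F > `primary_f` form the suprathreshold
#' graph and its connected components are the candidate subnetworks.
#' Family-wise error is controlled by permuting group labels: each
#' permutation repeats the edgewise tests and records the maximal
#' component size (number of edges); the corrected p-value of an
#' observed component of size S is (1 + #\{null maxima >= S\}) /
#' (n_perm + 1), so p >= 1/(n_perm + 1) always.
#'
#' @param z_list list of symmetric Fisher-z matrices, one per subject.
#' @param groups group label per subject (2 or more levels, each with at
#'   least 2 subjects).
#' @param primary_f primary cluster-defining F threshold (> 0).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param age,gender optional covariates; if both given the z values are
#'   residualized before testing (default pipeline behaviour).
#' @param alpha significance level for components.
#' @return object of class `nbs_result`: `f_matrix` (nodes x nodes),
#'   `primary_f`, `components` (list of edge-index matrices),
#'   `component_sizes`, `p_corrected`, `significant`, `null_sizes`,
#'   `pairs`, `groups`.
#' @export
nbs_anova <- function(z_list, groups, primary_f = 12, n_perm = 10000,
                      seed = NULL, age = NULL, gender = NULL, alpha = 0.05) {
  stop_if_not(primary_f > 0, "primary_f must be positive")
  groups <- as.factor(groups)
  nvec <- table(groups)
  stop_if_not(all(nvec >= 2L), "every group needs at least 2 subjects")
  stop_if_not(length(z_list) == length(groups),
              "one z matrix per subject required")
  fl <- flatten_z(z_list)
  X <- fl$X
  if (!is.null(age) && !is.null(gender)) {
    X <- residualize_edges(X, age, gender)
  }
  n <- nrow(X)
  G <- nlevels(groups)
  gi <- as.integer(groups)
  colsum <- colSums(X)
  colsq <- colSums(X^2)
  ind <- outer(gi, seq_len(G), "==") * 1  # n x G indicator
  fobs <- f_from_sums(crossprod(ind, X), as.numeric(nvec), colsum, colsq, n)

  supra <- which(fobs > primary_f)
  comps <- edge_components(fl$pairs[supra, , drop = FALSE], sizes = TRUE)
  comp_sizes <- vapply(comps, nrow, 0L)

  if (!is.null(seed)) set.seed(seed)
  null_sizes <- integer(n_perm)
  block <- 250L
  b0 <- 0L
  while (b0 < n_perm) {
    nb <- min(block, n_perm - b0)
    ## indicator columns for nb permutations at once -> one BLAS product
    M <- matrix(0, n, G * nb)
    for (b in seq_len(nb)) {
      gp <- gi[sample.int(n)]
      M[cbind(seq_len(n), (b - 1L) * G + gp)] <- 1
    }
    S <- crossprod(M, X)  # (G*nb) x E group sums
    for (b in seq_len(nb)) {
      fperm <- f_from_sums(S[(b - 1L) * G + seq_len(G), , drop = FALSE],
                           as.numeric(nvec), colsum, colsq, n)
      hits <- which(fperm > primary_f)
      null_sizes[b0 + b] <- if (length(hits))
        edge_components(fl$pairs[hits, , drop = FALSE]) else 0L
    }
    b0 <- b0 + nb
  }
  p_corr <- vapply(comp_sizes, function(s)
    (1 + sum(null_sizes >= s)) / (n_perm + 1), 0)

  Fm <- matrix(0, fl$n_nodes, fl$n_nodes)
  Fm[fl$pairs] <- fobs
  Fm <- Fm + t(Fm)
  structure(list(f_matrix = Fm, primary_f = primary_f,
                 components = comps, component_sizes = comp_sizes,
                 p_corrected = p_corr, significant = p_corr < alpha,
                 null_sizes = null_sizes, pairs = fl$pairs,
                 groups = groups, alpha = alpha),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: F > %g, %d permutations\n", x$primary_f,
              length(x$null_sizes)))
  if (!length(x$components)) {
    cat("  no suprathreshold component\n")
  } else {
    for (i in seq_along(x$components)) {
      cat(sprintf("  component %d: %d edges, corrected p = %.4g%s\n", i,
                  x$component_sizes[i], x$p_corrected[i],
                  if (x$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

#' Post hoc pairwise edge tests within significant NBS components
#'
#' Two-sample t-tests (pooled variance by default, Welch optionally) for
#' every group pair at every edge of every significant component.
#'
#' @param result an `nbs_result` with at least one significant component.
#' @param z_list the subject z matrices used for the NBS.
#' @param groups the group labels used for the NBS.
#' @param pooled use the pooled-variance t-test (default) or Welch.
#' @param significant_only restrict to components surviving correction
#'   (default); `FALSE` reports every suprathreshold component.
#' @return data frame: component, node_i, node_j, F, group pair, t, p.
#' @export
posthoc_edges <- function(result, z_list, groups, pooled = TRUE,
                          significant_only = TRUE) {
  use <- if (significant_only) which(result$significant)
         else seq_along(result$components)
  stop_if_not(length(use) > 0,
              if (significant_only) "no significant component"
              else "no suprathreshold component")
  groups <- as.factor(groups)
  levs <- levels(groups)
  out <- list()
  for (ci in use) {
    edges <- result$components[[ci]]
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      vals <- vapply(z_list, function(z) z[i, j], 0)
      for (p1 in seq_len(length(levs) - 1L)) {
        for (p2 in (p1 + 1L):length(levs)) {
          v1 <- vals[groups == levs[p1]]
          v2 <- vals[groups == levs[p2]]
          tp <- tryCatch({
            tt <- stats::t.test(v1, v2, var.equal = pooled)
            c(unname(tt$statistic), tt$p.value)
          }, error = function(e) {
            ## zero pooled variance: infinite separation or exact tie
            if (isTRUE(all.equal(mean(v1), mean(v2)))) c(0, 1)
            else c(sign(mean(v1) - mean(v2)) * Inf, 0)
          })
          out[[length(out) + 1L]] <- data.frame(
            component = ci, node_i = i, node_j = j,
            f = result$f_matrix[i, j],
            group_1 = levs[p1], group_2 = levs[p2],
            t = tp[1L], p = tp[2L])
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Write NBS component edge lists and the permutation null for audit
#' @param result an `nbs_result`.
#' @param dir output directory.
#' @param posthoc optional result of [posthoc_edges()].
#' @return `dir`, invisibly.
#' @export
write_nbs_result <- function(result, dir, posthoc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(result$components)) {
    comp_df <- do.call(rbind, lapply(seq_along(result$components), function(ci) {
      e <- result$components[[ci]]
      data.frame(component = ci, node_i = e[, 1L], node_j = e[, 2L],
                 f = result$f_matrix[e], p_corrected = result$p_corrected[ci])
    }))
    utils::write.table(comp_df, file.path(dir, "nbs_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(posthoc)) {
    utils::write.table(posthoc, file.path(dir, "nbs_posthoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(max_component_edges = result$null_sizes),
                     file.path(dir, "nbs_null_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
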