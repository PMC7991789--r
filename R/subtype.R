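## Psychometric patient subtyping: Ward hierarchical clustering with
## cluster-number selection by three validity indices, plus a
## concordance retest with k-medoids and fuzzy C-means.

scale_scores <- function(scores, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  X <- as.matrix(scores)
  if (method == "zscore") {
    scale(X)
  } else {
    apply(X, 2L, function(col) (col - min(col)) / max(max(col) - min(col),
                                                      .Machine$double.eps))
  }
}

## Calinski-Harabasz index: between/within dispersion ratio.
calinski_harabasz <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  gmean <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (cl in unique(labels)) {
    idx <- labels == cl
    cmean <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * sum((cmean - gmean)^2)
    ssw <- ssw + sum(sweep(X[idx, , drop = FALSE], 2L, cmean)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

## Davies-Bouldin index: mean over clusters of the worst
## (scatter_i + scatter_j) / centroid-distance ratio.
davies_bouldin <- function(X, labels) {
  cls <- sort(unique(labels))
  cent <- t(vapply(cls, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  scat <- vapply(cls, function(cl) {
    idx <- labels == cl
    mean(sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2L,
                            colMeans(X[idx, , drop = FALSE]))^2)))
  }, 0)
  k <- length(cls)
  ratios <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      (scat[i] + scat[j]) / max(d, .Machine$double.eps)
    }, 0))
  }, 0)
  mean(ratios)
}

mean_silhouette <- function(d, labels) {
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

#' Subtype patients from psychometric scales
#'
#' Z-scores the four anxiety/depression scales (SDS, SAS, SAI, TAI),
#' runs agglomerative hierarchical clustering with Euclidean distance
#' and Ward's minimum-variance criterion, evaluates each candidate
#' cluster number with the silhouette coefficient (max), the
#' Calinski-Harabasz index (max) and the Davies-Bouldin index (min),
#' and selects k by majority vote (ties toward smaller k). The cluster
#' with the higher mean normalized score is named FCAD (anxiety/
#' depressive subtype), the other FCNAD. A weak-structure flag is
#' emitted when the selected solution's mean silhouette falls below 0.4
#' (at most weak separation on the usual silhouette bands).
#'
#' @param scores patients x scales numeric matrix/data frame (no
#'   missing values).
#' @param k_range candidate cluster numbers.
#' @param scale_method `"zscore"` (default) or `"minmax"`.
#' @return object of class `cluster_solution`: `labels` (cluster index),
#'   `subtype` (FCAD/FCNAD per patient), `k`, `indices` (index-vs-k
#'   table with per-index votes), `linkage_heights` (merge heights for
#'   dendrogram reporting), `silhouette`, `weak_structure`, `hclust`.
#' @export
subtype_patients <- function(scores, k_range = 2:6,
                             scale_method = "zscore") {
  X <- scale_scores(scores, scale_method)
  stop_if_not(!anyNA(X), "missing scores are not allowed")
  stop_if_not(nrow(X) >= max(k_range) + 1L,
              "need at least max(k_range)+1 patients")
  d <- stats::dist(X, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  idx <- data.frame(k = k_range, silhouette = NA_real_, ch = NA_real_,
                    db = NA_real_)
  cuts <- list()
  for (r in seq_along(k_range)) {
    k <- k_range[r]
    lab <- stats::cutree(hc, k)
    cuts[[r]] <- lab
    idx$silhouette[r] <- mean_silhouette(d, lab)
    idx$ch[r] <- calinski_harabasz(X, lab)
    idx$db[r] <- davies_bouldin(X, lab)
  }
  vote <- c(silhouette = idx$k[which.max(idx$silhouette)],
            ch = idx$k[which.max(idx$ch)],
            db = idx$k[which.min(idx$db)])
  tal <- table(vote)
  k_sel <- min(as.integer(names(tal)[tal == max(tal)]))
  labels <- cuts[[match(k_sel, k_range)]]
  ## name clusters: higher mean normalized score -> FCAD
  severity <- vapply(seq_len(k_sel), function(cl)
    mean(X[labels == cl, , drop = FALSE]), 0)
  subtype <- rep("FCNAD", length(labels))
  subtype[labels == which.max(severity)] <- "FCAD"
  sil <- idx$silhouette[idx$k == k_sel]
  structure(list(labels = labels, subtype = subtype, k = k_sel,
                 indices = idx, votes = vote,
                 linkage_heights = hc$height,
                 silhouette = sil, weak_structure = sil < 0.4,
                 hclust = hc, scaled = X),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("psychometric subtyping: k = %d (votes: %s)\n", x$k,
              paste(sprintf("%s->%d", names(x$votes), x$votes),
                    collapse = ", ")))
  cat(sprintf("  sizes: %s; mean silhouette %.3f%s\n",
              paste(table(x$subtype), collapse = "/"), x$silhouette,
              if (x$weak_structure) " (weak structure)" else ""))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted-for-chance agreement computed from the
#' contingency table; 1 for identical partitions (up to relabeling),
#' about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stop_if_not(length(a) == length(b), "label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Retest subtype reliability with k-medoids and fuzzy C-means
#'
#' Runs PAM k-medoids and fuzzy C-means (fuzzifier m = 2, defuzzified by
#' maximal membership) on the same scaled scores at the fixed k and
#' reports each algorithm's adjusted Rand index against the reference
#' (Ward) labels.
#'
#' @param scores patients x scales matrix.
#' @param k cluster count fixed by [subtype_patients()].
#' @param reference_labels labels to compare against (e.g. the Ward
#'   solution).
#' @param seed optional seed (fuzzy C-means initialization).
#' @param scale_method as in [subtype_patients()].
#' @return list with `ari_kmedoids`, `ari_fuzzy_cmeans`, the two label
#'   vectors, and `converged` (fuzzy C-means convergence flag).
#' @export
retest_concordance <- function(scores, k, reference_labels, seed = NULL,
                               scale_method = "zscore") {
  X <- scale_scores(scores, scale_method)
  if (!is.null(seed)) set.seed(seed)
  pam_fit <- cluster::pam(X, k = k, metric = "euclidean")
  iter_max <- 200L
  cm_fit <- e1071::cmeans(X, centers = k, m = 2, iter.max = iter_max)
  cm_lab <- apply(cm_fit$membership, 1L, which.max)
  list(ari_kmedoids = adjusted_rand(pam_fit$clustering, reference_labels),
       ari_fuzzy_cmeans = adjusted_rand(cm_lab, reference_labels),
       labels_kmedoids = pam_fit$clustering,
       labels_fuzzy_cmeans = cm_lab,
       converged = cm_fit$iter < iter_max)
}
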