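test_that("greedy modularity on canonical structures", {
  ## two disjoint 5-cliques: Q = 0.5 for the 2-block partition
  A <- matrix(0L, 10L, 10L)
  A[1:5, 1:5] <- 1L; A[6:10, 6:10] <- 1L; diag(A) <- 0L
  p <- greedy_modularity(A)
  expect_equal(p$n_modules, 2L)
  expect_equal(sort(p$sizes), c(5L, 5L))
  expect_equal(p$q, 0.5, tolerance = 1e-12)
  ## complete graph: one module, Q = 0
  K6 <- matrix(1L, 6L, 6L); diag(K6) <- 0L
  pk <- greedy_modularity(K6)
  expect_equal(pk$n_modules, 1L)
  expect_equal(pk$q, 0, tolerance = 1e-12)
  expect_error(greedy_modularity(matrix(0L, 4L, 4L)), "no edges")
})

test_that("merge-tracked Q equals the definition formula and the oracle", {
  set.seed(14)
  for (rep in 1:10) {
    A <- random_graph(25L, runif(1, 0.15, 0.4))
    p <- greedy_modularity(A)
    expect_equal(p$q, modularity_q(A, p$labels), tolerance = 1e-12)
    expect_equal(p$q, oracle_q(A, p$labels), tolerance = 1e-12)
    expect_equal(sum(p$sizes), 25L)
  }
})

test_that("greedy partitions agree with an independent implementation", {
  ## cross-check against igraph fast-greedy on well-separated structure
  set.seed(15)
  for (rep in 1:5) {
    blocks <- rep(1:3, each = 8L)
    P <- ifelse(outer(blocks, blocks, "=="), 0.85, 0.08)
    A <- matrix(0L, 24L, 24L)
    up <- which(upper.tri(A))
    A[up] <- as.integer(runif(length(up)) < P[up])
    A <- A + t(A)
    if (any(rowSums(A) == 0)) next
    p <- greedy_modularity(A)
    ref <- igraph::cluster_fast_greedy(
      igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
    expect_equal(adjusted_rand(p$labels, igraph::membership(ref)), 1)
  }
})

test_that("planted 4-block partitions are recovered across seeds", {
  blocks <- rep(1:4, each = 10L)
  P <- ifelse(outer(blocks, blocks, "=="), 0.9, 0.05)
  hits <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    A <- matrix(0L, 40L, 40L)
    up <- which(upper.tri(A))
    A[up] <- as.integer(runif(length(up)) < P[up])
    A <- A + t(A)
    if (any(rowSums(A) == 0)) next
    p <- greedy_modularity(A)
    if (isTRUE(all.equal(adjusted_rand(p$labels, blocks), 1))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of seeded runs
})

test_that("modular metrics follow their defining formulas", {
  ## 6 nodes, two modules of 3; node 1 has one edge into each module
  A <- matrix(0L, 6L, 6L)
  ed <- rbind(c(1, 2), c(1, 4), c(2, 3), c(4, 5), c(5, 6))
  for (k in seq_len(nrow(ed))) A[ed[k, 1], ed[k, 2]] <- A[ed[k, 2], ed[k, 1]] <- 1L
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  mm <- modular_metrics(A, labels)
  ## degree-2 node with one edge per module: participation = 1 - 2*(1/2)^2
  expect_equal(mm$participation[1L], 0.5)
  ## all edges inside own module: participation 0
  expect_equal(mm$participation[3L], 0)
  expect_equal(mm$participation[6L], 0)
  ## intra-module density: module 2 has edges (4,5),(5,6) of 3 possible
  expect_equal(mm$module_conn["2", "2"], 2 / 3)
  ## inter-module density: 1 edge of 9 possible
  expect_equal(mm$module_conn["1", "2"], 1 / 9)
  ## within-degree normalization: module mean is 1 by construction
  kin <- c(1, 2, 1)  # within-module degrees of nodes 1..3
  expect_equal(mm$within_degree[1:3], kin / mean(kin))
  ## single-module degenerate case: intra = overall density
  mm1 <- modular_metrics(A, rep(1L, 6L))
  expect_equal(mm1$module_conn["1", "1"], sum(A) / (6 * 5))
  expect_equal(dim(mm1$module_conn), c(1L, 1L))
})

test_that("participation is invariant to module relabeling", {
  set.seed(16)
  A <- random_graph(20L, 0.3)
  labels <- sample(1:4, 20L, replace = TRUE)
  relab <- c(3L, 1L, 4L, 2L)[labels]
  m1 <- modular_metrics(A, labels)
  m2 <- modular_metrics(A, relab)
  expect_equal(m1$participation, m2$participation)
})

test_that("weighted module connectivity uses mean Fisher z", {
  A <- matrix(0L, 4L, 4L)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  z <- matrix(0.2, 4L, 4L); diag(z) <- 0
  z[1, 2] <- z[2, 1] <- 0.8
  mm <- modular_metrics(A, c(1L, 1L, 2L, 2L), z = z)
  expect_equal(mm$module_conn["1", "1"], 0.8)  # single within pair
  expect_equal(mm$module_conn["1", "2"], 0.2)
})

test_that("HC reference partitions recover the planted 7-module structure", {
  planted <- c(50L, 50L, 48L, 21L, 22L, 27L, 28L)
  hits <- 0L
  n_seeds <- 5L
  for (seed in seq_len(n_seeds)) {
    spec <- cohort_spec(group_sizes = c(HC = 43L, FCNAD = 1L, FCAD = 1L),
                        seed = 1000L + seed)
    co <- suppressMessages(generate_cohort(spec))
    hc <- which(co$subjects$group == "HC")
    graphs <- lapply(hc, function(i)
      binarize(correlation_matrix(
        clean_timeseries(co$timeseries[[i]], co$motion[[i]])$ts), 0.20))
    res <- suppressWarnings(
      hc_reference_partitions(graphs, atlas = co$atlas))
    best <- res$best
    if (best$n_modules == 7L &&
          all(sort(best$sizes) == sort(planted))) hits <- hits + 1L
    ## monotone nesting of occurrence graphs across tau
    g70 <- group_occurrence_graph(graphs, 0.70)$adjacency
    g50 <- group_occurrence_graph(graphs, 0.50)$adjacency
    expect_true(all(g50[g70 == 1L] == 1L))
  }
  expect_gte(hits, n_seeds)  # recovery is essentially deterministic here
})

test_that("identical control graphs give identical partitions at every tau", {
  set.seed(17)
  A <- random_graph(18L, 0.25)
  graphs <- replicate(8, binary_graph(A), simplify = FALSE)
  res <- suppressMessages(suppressWarnings(
    hc_reference_partitions(graphs, tau_grid = c(0.5, 0.6, 0.7))))
  labs <- lapply(res$partitions, `[[`, "labels")
  for (l in labs[-1L]) expect_equal(l, labs[[1L]])
})
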