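## Simulate subject Fisher-z matrices edge by edge: baseline N(mu, sd)
## with an optional shift on selected edges in one group.
sim_z_cohort <- function(n_nodes, groups, shift_edges = NULL,
                         shift_group = NULL, delta = 0, mu = 0.2, sd = 0.1) {
  lapply(seq_along(groups), function(i) {
    z <- matrix(0, n_nodes, n_nodes)
    up <- upper.tri(z)
    z[up] <- rnorm(sum(up), mu, sd)
    if (!is.null(shift_edges) && groups[i] == shift_group) {
      for (k in seq_len(nrow(shift_edges))) {
        z[shift_edges[k, 1L], shift_edges[k, 2L]] <-
          z[shift_edges[k, 1L], shift_edges[k, 2L]] + delta
      }
    }
    z <- z + t(z)
    z
  })
}

test_that("component extraction matches a union-find oracle", {
  ## hand-built suprathreshold mask: 6 edges forming two components
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(6, 7), c(7, 8), c(6, 8))
  groups <- rep(c("a", "b", "c"), each = 4L)
  set.seed(1)
  zl <- sim_z_cohort(10L, groups)
  ## force exactly these edges over threshold via a huge group shift
  for (i in which(groups == "a")) {
    for (k in seq_len(nrow(pairs))) {
      zl[[i]][pairs[k, 1L], pairs[k, 2L]] <-
        zl[[i]][pairs[k, 1L], pairs[k, 2L]] + 50
      zl[[i]][pairs[k, 2L], pairs[k, 1L]] <- zl[[i]][pairs[k, 1L], pairs[k, 2L]]
    }
  }
  res <- nbs_anova(zl, groups, primary_f = 500, n_perm = 50, seed = 2L)
  expect_equal(sort(res$component_sizes), c(3L, 3L))
  expect_equal(max(res$component_sizes),
               oracle_max_component_edges(pairs))
  ## every reported component edge is suprathreshold
  for (comp in res$components) {
    expect_true(all(res$f_matrix[comp] > 500))
  }
})

test_that("permutation p-values respect the (b+1)/(m+1) floor and seed", {
  set.seed(3)
  groups <- rep(c("a", "b", "c"), each = 6L)
  zl <- sim_z_cohort(12L, groups, shift_edges = rbind(c(1, 2)),
                     shift_group = "a", delta = 3)
  r1 <- nbs_anova(zl, groups, primary_f = 12, n_perm = 99, seed = 7L)
  r2 <- nbs_anova(zl, groups, primary_f = 12, n_perm = 99, seed = 7L)
  expect_identical(r1$p_corrected, r2$p_corrected)
  expect_identical(r1$null_sizes, r2$null_sizes)
  expect_true(all(r1$p_corrected >= 1 / 100))
  expect_gte(length(r1$components), 1L)
})

test_that("post hoc pooled t matches the closed-form formula", {
  ## printed 4-subject fixture, 2 vs 2
  x <- c(1.0, 1.4); y <- c(0.2, 0.6)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 2
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  groups <- c("a", "a", "b", "b")
  zl <- lapply(seq_len(4L), function(i) {
    z <- matrix(0, 3L, 3L)
    z[1, 2] <- z[2, 1] <- c(x, y)[i]
    z[1, 3] <- z[3, 1] <- 50 * (groups[i] == "a")  # drives the component
    z
  })
  res <- nbs_anova(zl, groups, primary_f = 1, n_perm = 20, seed = 1L)
  ph <- posthoc_edges(res, zl, groups, significant_only = FALSE)
  row <- ph[ph$node_i == 1 & ph$node_j == 2, ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  ## identical groups give t ~ 0 on average
  set.seed(9)
  g2 <- rep(c("a", "b"), each = 10L)
  zl2 <- sim_z_cohort(6L, g2)
  tt <- sapply(1:5, function(k)
    stats::t.test(sapply(zl2[g2 == "a"], function(z) z[1, k + 1]),
                  sapply(zl2[g2 == "b"], function(z) z[1, k + 1]),
                  var.equal = TRUE)$statistic)
  expect_lt(mean(abs(tt)), 2)
  ## extreme separation
  set.seed(10)
  zl3 <- sim_z_cohort(4L, rep(c("a", "b", "c"), each = 30L),
                      shift_edges = rbind(c(1, 2)), shift_group = "a",
                      delta = 1, sd = 0.1)
  res3 <- nbs_anova(zl3, rep(c("a", "b", "c"), each = 30L),
                    primary_f = 12, n_perm = 99, seed = 3L)
  ph3 <- posthoc_edges(res3, zl3, rep(c("a", "b", "c"), each = 30L),
                       significant_only = FALSE)
  expect_lt(min(ph3$p[ph3$group_1 == "a"]), 1e-10)
})

test_that("edgewise F equals the sum-of-squares oracle", {
  set.seed(11)
  groups <- rep(c("a", "b", "c"), times = c(5L, 6L, 7L))
  zl <- sim_z_cohort(8L, groups)
  res <- nbs_anova(zl, groups, primary_f = 1e6, n_perm = 1, seed = 1L)
  vals <- sapply(zl, function(z) z[2, 5])
  expect_equal(res$f_matrix[2, 5], oracle_anova_f(vals, groups),
               tolerance = 1e-10)
})

test_that("covariate residualization changes the NBS inputs as an option", {
  set.seed(12)
  groups <- rep(c("a", "b", "c"), each = 5L)
  zl <- sim_z_cohort(6L, groups)
  age <- rnorm(15L, 40, 10)
  gender <- sample(c("M", "F"), 15L, replace = TRUE)
  plain <- nbs_anova(zl, groups, primary_f = 1e6, n_perm = 1, seed = 1L)
  resid <- nbs_anova(zl, groups, primary_f = 1e6, n_perm = 1, seed = 1L,
                     age = age, gender = gender)
  expect_false(isTRUE(all.equal(plain$f_matrix, resid$f_matrix)))
  expect_error(nbs_anova(zl, groups, primary_f = -1), "positive")
  expect_error(nbs_anova(zl[1:3], c("a", "a", "b")), "at least 2")
})
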