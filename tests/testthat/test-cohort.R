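test_that("cohort generation is bit-identical under a fixed seed", {
  spec <- small_spec(seed = 42L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$timeseries[[5L]]$data, b$timeseries[[5L]]$data)
  expect_identical(a$motion[[5L]]$params, b$motion[[5L]]$params)
})

test_that("sampled correlations recover the generating parameters", {
  ## long series, no planted effects: within-module sample correlations
  ## must sit within Monte-Carlo error of the target
  spec <- cohort_spec(group_sizes = c(HC = 1L, FCNAD = 1L, FCAD = 1L),
                      n_nodes = 40L, module_sizes = c(10L, 10L, 5L, 5L, 4L, 3L, 3L),
                      n_frames = 10000L, within_r = 0.3, between_r = 0,
                      effect_map = list(), n_spikes = 0L, drift_sd = 0,
                      seed = 42L)
  co <- generate_cohort(spec)
  X <- co$timeseries[[1L]]$data
  r <- cor(X)
  mod <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  within <- outer(mod, mod, "==") & upper.tri(r)
  between <- !outer(mod, mod, "==") & upper.tri(r)
  expect_lt(abs(mean(r[within]) - 0.3), 0.03)
  expect_lt(abs(mean(r[between])), 0.03)
})

test_that("psychometric draws match the configured group distributions", {
  co <- generate_cohort(cohort_spec(seed = 42L))
  sds_fcad <- co$subjects$sds[co$subjects$group == "FCAD"]
  ## group mean within 3 SE of the configured FCAD depression mean
  expect_lt(abs(mean(sds_fcad) - 69.0244), 3 * 1.4673)
  ## scale bounds respected
  for (sc in c("sds", "sas", "sai", "tai")) {
    expect_true(all(co$subjects[[sc]] >= 20 & co$subjects[[sc]] <= 80))
  }
  pat <- co$subjects$group != "HC"
  expect_true(all(co$subjects$abdominal_pain[pat] >= 0 &
                    co$subjects$abdominal_pain[pat] <= 100))
  expect_true(all(is.na(co$subjects$abdominal_pain[!pat])))
  ## gender drawn to match the configured counts exactly
  tab <- table(co$subjects$group, co$subjects$gender)
  expect_equal(unname(tab["HC", c("M", "F")]), c(18L, 25L))
  expect_equal(unname(tab["FCNAD", c("M", "F")]), c(16L, 26L))
  expect_equal(unname(tab["FCAD", c("M", "F")]), c(10L, 31L))
})

test_that("group target correlation matrices are symmetric PSD", {
  spec <- cohort_spec()
  for (g in c("HC", "FCNAD", "FCAD")) {
    R <- group_correlation(spec, g)
    expect_equal(R, t(R))
    expect_true(all(diag(R) == 1))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("non-positive-definite planted targets are repaired with a warning", {
  spec <- cohort_spec(
    within_r = 0.05, between_r = 0,
    effect_map = list(cohort_effect("block_add", groups = "FCAD",
                                    modules = c("SN", "SMN"), delta = 0.9)))
  expect_warning(R <- group_correlation(spec, "FCAD"), "repaired")
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(R)), rep(1, spec$n_nodes))
})

test_that("planted SN-SMN inter-module increment is recoverable in Fisher z", {
  base_args <- list(group_sizes = c(HC = 20L, FCNAD = 1L, FCAD = 20L),
                    n_nodes = 60L,
                    module_sizes = c(12L, 12L, 12L, 6L, 6L, 6L, 6L),
                    n_frames = 195L, n_spikes = 0L, drift_sd = 0,
                    seed = 42L)
  spec <- do.call(cohort_spec, base_args)
  co <- generate_cohort(spec)
  atlas <- co$atlas
  sn <- atlas$module == "SN"; smn <- atlas$module == "SMN"
  block_mean <- function(i) {
    z <- atanh(pmin(pmax(cor(co$timeseries[[i]]$data), -1 + 1e-7), 1 - 1e-7))
    mean(z[sn, smn])
  }
  grp <- co$subjects$group
  z_hc <- vapply(which(grp == "HC"), block_mean, 0)
  z_pat <- vapply(which(grp == "FCAD"), block_mean, 0)
  ## planted sign: patients carry a positive SN-SMN increment
  expect_gt(mean(z_pat) - mean(z_hc), 0)
})

test_that("motion traces obey spikes, zero-motion and seeding", {
  ## zero amplitude, no spikes: FD identically zero
  m0 <- generate_motion(50L, amplitude = 0, seed = 1L)
  expect_equal(m0$fd, rep(0, 50L))
  ## constructed exceedance at the spike frame
  m1 <- generate_motion(195L, spike_frames = 50L, seed = 1L, spike_mm = 2)
  expect_gt(m1$fd[50L], 0.5)
  ## seeded reproducibility
  m2 <- generate_motion(195L, spike_frames = 50L, seed = 1L, spike_mm = 2)
  expect_identical(m1$params, m2$params)
  expect_error(generate_motion(20L, spike_frames = 30L), "out of range")
})

test_that("cohort round-trips through the delimited-text format", {
  spec <- small_spec(seed = 7L)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects$sds, co$subjects$sds)
  expect_equal(back$atlas, co$atlas)
  expect_equal(back$timeseries[[3L]]$data, co$timeseries[[3L]]$data,
               tolerance = 1e-5)
  expect_equal(back$motion[[3L]]$fd, co$motion[[3L]]$fd, tolerance = 1e-2)
})
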