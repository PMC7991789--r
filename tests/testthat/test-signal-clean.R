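test_that("framewise displacement follows the 50 mm projection", {
  ## constant parameters: no motion
  p <- matrix(0.3, 10L, 6L)
  expect_equal(compute_fd(p), rep(0, 10L))
  ## +0.1 mm on each translation at one frame: FD = 0.3 mm
  p <- matrix(0, 10L, 6L)
  p[5:10, 1:3] <- 0.1
  expect_equal(compute_fd(p)[5L], 0.3)
  ## 0.01 rad on one rotation axis: 0.01 * 50 = 0.5 mm
  p <- matrix(0, 10L, 6L)
  p[5:10, 4L] <- 0.01
  expect_equal(compute_fd(p)[5L], 0.5)
  expect_equal(compute_fd(matrix(0, 10L, 6L))[1L], 0)
  expect_error(compute_fd(matrix(0, 10L, 4L)), "6 columns")
})

test_that("scrubbing applies the conjunction rule and reports fractions", {
  n <- 195L
  set.seed(1)
  ts <- roi_timeseries(matrix(rnorm(n * 5L, mean = 100), n, 5L), 2)
  params <- matrix(0, n, 6L)
  ## three frames exceed both criteria; one frame exceeds FD only
  both <- c(50L, 90L, 130L)
  params[both, 1L] <- 5
  params[both + 1L, 1L] <- 0   # jump back: FD spike only at the jump frames
  fd <- compute_fd(params)
  dvars <- rep(0.1, n)
  dvars[both] <- 1.2
  fd_only <- 170L
  fd[fd_only] <- 0.6
  trace <- structure(list(params = params, fd = fd, dvars = dvars),
                     class = "motion_trace")
  sc <- scrub(ts, trace)
  expect_equal(sc$scrubbed_fraction, 3 / 195, tolerance = 1e-12)
  expect_false(sc$flagged)
  ## the AND rule keeps the FD-only frame
  expect_true(sc$ts$valid_mask[fd_only])
  expect_false(any(sc$ts$valid_mask[both]))
  ## the OR rule drops it
  sc_or <- scrub(ts, trace, rule = "or")
  expect_false(sc_or$ts$valid_mask[fd_only])
  ## clean trace: nothing scrubbed
  clean <- structure(list(params = matrix(0, n, 6L), fd = rep(0, n),
                          dvars = rep(0, n)), class = "motion_trace")
  sc0 <- scrub(ts, clean)
  expect_equal(sc0$scrubbed_fraction, 0)
  expect_true(all(sc0$ts$valid_mask))
})

test_that("subjects losing more than 5% of frames are flagged", {
  n <- 100L
  ts <- roi_timeseries(matrix(rnorm(n * 4L, mean = 100), n, 4L), 2)
  fd <- rep(0, n); dvars <- rep(0, n)
  bad <- 1:10
  fd[bad] <- 1; dvars[bad] <- 1
  trace <- structure(list(params = matrix(0, n, 6L), fd = fd, dvars = dvars),
                     class = "motion_trace")
  expect_warning(sc <- scrub(ts, trace), "exceeds")
  expect_true(sc$flagged)
})

test_that("nuisance regression residuals are orthogonal to the design", {
  set.seed(42)
  n <- 120L
  trace <- generate_motion(n, seed = 3L)
  wm <- rnorm(n); csf <- rnorm(n)
  X <- matrix(rnorm(n * 6L), n, 6L)
  ## one node is exactly the WM signal: its residual must vanish
  X[, 3L] <- wm
  ts <- roi_timeseries(X, 2, wm = wm, csf = csf)
  res <- nuisance_regress(ts, trace)
  expect_lt(max(abs(res$data[, 3L])), 1e-8)
  ## residuals orthogonal to every design column (28 columns)
  design <- cbind(1, seq_len(n), trace$params,
                  rbind(0, trace$params[-n, ]), trace$params^2,
                  rbind(0, trace$params[-n, ])^2, wm, csf)
  ip <- crossprod(design, res$data)
  expect_lt(max(abs(ip)), 1e-6)
  ## a mean-centered signal orthogonal to all regressors passes through
  v <- qr.resid(qr(design), rnorm(n))
  ts2 <- roi_timeseries(cbind(v, v), 2, wm = wm, csf = csf)
  res2 <- nuisance_regress(ts2, trace)
  expect_equal(res2$data[, 1L], v, tolerance = 1e-10)
})

test_that("collinear nuisance columns are dropped with a warning", {
  n <- 60L
  trace <- generate_motion(n, seed = 4L)
  wm <- rnorm(n)
  ts <- roi_timeseries(matrix(rnorm(n * 3L), n, 3L), 2, wm = wm, csf = wm)
  expect_warning(res <- nuisance_regress(ts, trace), "collinear")
  expect_equal(nrow(res$data), n)
})

test_that("band-pass filter passes 0.04 Hz and rejects 0.2 Hz at TR = 2 s", {
  n <- 195L
  tt <- (seq_len(n) - 1) * 2
  inband <- sin(2 * pi * 0.04 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  ts <- roi_timeseries(cbind(inband, outband, 0), 2)
  filt <- bandpass(ts)
  pow <- function(x) sum(x^2)
  expect_gt(pow(filt$data[, 1L]) / pow(inband), 0.99)
  expect_lt(pow(filt$data[, 2L]) / pow(outband), 0.01)
  expect_equal(filt$data[, 3L], rep(0, n), tolerance = 1e-10)
  ## invalid frames are interpolated for filtering, then re-censored by
  ## the cleaning wrapper (mask is preserved by bandpass itself)
  ts$valid_mask[10:12] <- FALSE
  expect_silent(filt2 <- bandpass(ts))
  expect_equal(filt2$valid_mask, ts$valid_mask)
  expect_error(bandpass(roi_timeseries(cbind(rnorm(20)), 2), 1e-6, 1e-5),
               "no Fourier bin")
  expect_error(bandpass(roi_timeseries(cbind(rnorm(20)), 2), 0.01, 0.4),
               "Nyquist")
})

test_that("cleaning leaves already-clean band-limited noise nearly unchanged", {
  set.seed(5)
  n <- 195L
  ## white noise pre-filtered to the passband, no motion, no nuisance share
  raw <- matrix(rnorm(n * 4L), n, 4L)
  pre <- bandpass(roi_timeseries(raw, 2))
  trace <- structure(list(params = matrix(0, n, 6L), fd = rep(0, n),
                          dvars = rep(0, n)), class = "motion_trace")
  ts <- pre
  ts$wm <- rnorm(n); ts$csf <- rnorm(n)
  ## the all-zero motion expansion is collinear by construction
  out <- suppressWarnings(clean_timeseries(ts, trace))
  ## residualizing on noise regressors perturbs only slightly
  expect_gt(cor(as.vector(out$ts$data), as.vector(pre$data)), 0.9)
  expect_equal(out$qc$scrubbed_fraction, 0)
})
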