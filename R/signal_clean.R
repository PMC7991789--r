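#' Framewise displacement from rigid-body parameters
#'
#' FD(t) = sum of absolute frame-to-frame differences of the three
#' translations (mm) plus the three rotations (radians) projected onto a
#' 50 mm sphere. The first frame is 0 by convention.
#'
#' @param params frames x 6 matrix: translations (mm) then rotations (rad).
#' @return numeric vector of per-frame displacement in mm.
#' @export
compute_fd <- function(params) {
  stop_if_not(ncol(params) == 6L,
              "motion parameters must have 6 columns, got %d", ncol(params))
  stop_if_not(nrow(params) >= 2L, "need at least 2 frames")
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS: per-frame BOLD signal change
#'
#' Root-mean-square across nodes of the frame-difference signal,
#' expressed as a percentage of the grand mean signal. The first frame is
#' 0 by convention.
#'
#' @param data frames x nodes signal matrix (raw, with its mean level).
#' @return numeric vector, percent of grand mean signal.
#' @export
compute_dvars <- function(data) {
  stop_if_not(nrow(data) >= 2L, "need at least 2 frames")
  gm <- mean(data)
  stop_if_not(is.finite(gm) && abs(gm) > .Machine$double.eps^0.5,
              "grand mean signal is ~0; DVARS (%% of mean) undefined")
  rms <- sqrt(rowMeans(diff(data)^2))
  c(0, 100 * rms / abs(gm))
}

#' Motion scrubbing
#'
#' Invalidates frames exceeding both (rule `"and"`, the default) or
#' either (rule `"or"`) of the framewise-displacement and DVARS
#' thresholds. Subjects losing more than `max_fraction` of frames are
#' flagged (with a warning), not silently passed.
#'
#' @param ts a [roi_timeseries()].
#' @param trace a `motion_trace` aligned to `ts` (its `dvars` field is
#'   computed from `ts` if absent).
#' @param fd_thresh FD threshold in mm.
#' @param dvars_thresh DVARS threshold in percent.
#' @param rule `"and"` (both criteria must be exceeded) or `"or"`.
#' @param max_fraction flag threshold on the scrubbed fraction.
#' @return list with `ts` (updated `valid_mask`), `scrubbed_fraction`,
#'   and `flagged`.
#' @export
scrub <- function(ts, trace, fd_thresh = 0.5, dvars_thresh = 0.5,
                  rule = c("and", "or"), max_fraction = 0.05) {
  rule <- match.arg(rule)
  stop_if_not(nrow(trace$params) == nrow(ts$data),
              "motion trace and time series have different frame counts")
  dvars <- trace$dvars %||% compute_dvars(ts$data)
  bad <- if (rule == "and") {
    trace$fd > fd_thresh & dvars > dvars_thresh
  } else {
    trace$fd > fd_thresh | dvars > dvars_thresh
  }
  newly <- bad & ts$valid_mask
  ts$valid_mask <- ts$valid_mask & !bad
  frac <- sum(bad) / nrow(ts$data)
  flagged <- frac > max_fraction
  if (flagged) {
    warning(sprintf("subject %s: scrubbed fraction %.1f%% exceeds %.0f%%",
                    ts$subject_id, 100 * frac, 100 * max_fraction))
  }
  list(ts = ts, scrubbed_fraction = frac, flagged = flagged,
       n_scrubbed = sum(newly))
}

## Friston-24 expansion: 6 parameters, their one-frame lags, and the
## squares of both.
friston24 <- function(params) {
  lag <- rbind(0, params[-nrow(params), , drop = FALSE])
  cbind(params, lag, params^2, lag^2)
}

#' Nuisance regression of ROI signals
#'
#' Ordinary least-squares residuals of every node signal against an
#' intercept, a linear trend, the 24-parameter motion expansion (six
#' rigid-body parameters, their one-frame lags, and squares of both),
#' and the white-matter and CSF signals. Collinear columns are dropped
#' with a warning. Residuals are exactly orthogonal to every retained
#' regressor.
#'
#' @param ts a [roi_timeseries()].
#' @param trace a `motion_trace` aligned to `ts`.
#' @param wm,csf nuisance signals; default to those stored in `ts`.
#' @return a [roi_timeseries()] of residuals (mask preserved).
#' @export
nuisance_regress <- function(ts, trace, wm = ts$wm, csf = ts$csf) {
  nfr <- nrow(ts$data)
  stop_if_not(nrow(trace$params) == nfr, "regressors not aligned to frames")
  X <- cbind(intercept = 1, trend = seq_len(nfr) - (nfr + 1) / 2,
             friston24(trace$params))
  if (!is.null(wm)) {
    stop_if_not(length(wm) == nfr, "wm signal not aligned to frames")
    X <- cbind(X, wm = wm)
  }
  if (!is.null(csf)) {
    stop_if_not(length(csf) == nfr, "csf signal not aligned to frames")
    X <- cbind(X, csf = csf)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(drop),
                    paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, ts$data)
  ts$data <- res
  ts
}

#' Band-pass filtering of ROI signals
#'
#' Discrete-Fourier-transform filtering with a hard rectangular mask
#' retaining frequencies in `[low, high]` Hz (deterministic, exact band
#' edges). Invalid frames are linearly interpolated before filtering and
#' re-invalidated afterwards, so censored frames do not leak artefacts
#' into the passband.
#'
#' @param ts a [roi_timeseries()].
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @return filtered [roi_timeseries()].
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08) {
  nfr <- nrow(ts$data)
  nyquist <- 1 / (2 * ts$tr_seconds)
  stop_if_not(high < nyquist, "high edge %.3g Hz is not below Nyquist %.3g Hz",
              high, nyquist)
  stop_if_not(low < high, "low edge must be below high edge")
  freqs <- seq(0, nfr - 1) / (nfr * ts$tr_seconds)
  freqs <- pmin(freqs, 1 / ts$tr_seconds - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  stop_if_not(any(keep),
              "no Fourier bin falls inside [%.3g, %.3g] Hz for %d frames",
              low, high, nfr)
  X <- ts$data
  if (!all(ts$valid_mask)) {
    tt <- seq_len(nfr)
    ok <- which(ts$valid_mask)
    stop_if_not(length(ok) >= 2L, "fewer than 2 valid frames to interpolate from")
    X <- apply(X, 2L, function(col)
      stats::approx(tt[ok], col[ok], xout = tt, rule = 2)$y)
  }
  f <- stats::mvfft(X)
  f[!keep, ] <- 0
  ts$data <- Re(stats::mvfft(f, inverse = TRUE)) / nfr
  ts
}

#' Full temporal cleaning of one subject
#'
#' Applies the pipeline in the fixed order: nuisance regression (which
#' includes demeaning/detrending) -> scrub flagging -> interpolation +
#' band-pass filtering -> re-censoring. Downstream correlation uses
#' valid frames only.
#'
#' @param ts a [roi_timeseries()].
#' @param trace matching `motion_trace`.
#' @param fd_thresh,dvars_thresh,rule scrubbing parameters, see [scrub()].
#' @param low,high band edges in Hz.
#' @return list with `ts` (cleaned), `qc` (per-subject quality report:
#'   mean/max FD, scrubbed fraction, flag).
#' @export
clean_timeseries <- function(ts, trace, fd_thresh = 0.5, dvars_thresh = 0.5,
                             rule = "and", low = 0.01, high = 0.08) {
  ts <- nuisance_regress(ts, trace)
  sc <- scrub(ts, trace, fd_thresh, dvars_thresh, rule)
  ts <- bandpass(sc$ts, low, high)
  ts$valid_mask <- sc$ts$valid_mask
  qc <- list(subject_id = ts$subject_id,
             mean_fd = mean(trace$fd), max_fd = max(trace$fd),
             scrubbed_fraction = sc$scrubbed_fraction,
             flagged = sc$flagged)
  list(ts = ts, qc = qc)
}

#' Write per-subject QC reports as JSON
#' @param qc_list list of QC reports from [clean_timeseries()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc_list, path) {
  jsonlite::write_json(qc_list, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
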