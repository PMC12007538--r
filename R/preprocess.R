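#' 4D Power Doppler volume
#'
#' The common currency of the pipeline: a (x, y, z, t) array of Power Doppler
#' values with the volume TR, the per-slice within-TR acquisition onsets from
#' the scan schedule, and a voxel-to-mm affine.
#'
#' @param values Numeric 4D array (x, y, z, t).
#' @param tr Volume repetition time, s.
#' @param slice_onsets Per-slice acquisition onset within one TR, s
#'   (length = z dim). Default all zero.
#' @param affine 4x4 voxel-to-mm matrix; default 0.1 mm isotropic in-plane
#'   with the schedule's slice step if given.
#' @return Object of class `pd_volume`.
#' @export
pd_volume <- function(values, tr, slice_onsets = NULL, affine = NULL) {
  d <- dim(values)
  if (length(d) != 4L) stop("values must be a 4D (x, y, z, t) array")
  if (is.null(slice_onsets)) slice_onsets <- rep(0, d[3])
  if (length(slice_onsets) != d[3]) {
    stop("slice_onsets length must equal the z dimension")
  }
  if (any(slice_onsets < 0 | slice_onsets >= tr)) {
    stop("slice onsets must lie in [0, TR)")
  }
  if (is.null(affine)) {
    affine <- diag(c(0.1, 0.1, 0.525, 1))
  }
  structure(list(values = values, tr = tr, slice_onsets = slice_onsets,
                 affine = affine), class = "pd_volume")
}

#' @export
print.pd_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("pd_volume: %d x %d x %d voxels, %d volumes, TR %.3f s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Number of time points of a pd_volume
#' @param vol A [pd_volume()].
#' @return Integer count of volumes.
#' @export
n_volumes <- function(vol) dim(vol$values)[4]

#' Slice-timing correction
#'
#' Resamples every slice's time series onto the sampling grid of the first
#' acquired position (onset 0) by linear interpolation, so all slices share a
#' common time base. Endpoints beyond the recorded range are held at the edge
#' value.
#'
#' @param vol A [pd_volume()] with known slice onsets.
#' @return A [pd_volume()] with uniform (zero) slice onsets.
#' @export
slice_timing_correct <- function(vol) {
  stopifnot(inherits(vol, "pd_volume"))
  d <- dim(vol$values)
  if (d[4] < 2L) stop("slice-timing correction needs at least 2 time points")
  t_target <- (seq_len(d[4]) - 1) * vol$tr
  out <- vol$values
  for (iz in seq_len(d[3])) {
    dt <- vol$slice_onsets[iz]
    if (dt == 0) next
    t_actual <- t_target + dt
    plane <- matrix(vol$values[, , iz, ], d[1] * d[2], d[4])
    corrected <- t(apply(plane, 1, function(y) {
      stats::approx(t_actual, y, xout = t_target, rule = 2)$y
    }))
    out[, , iz, ] <- array(corrected, c(d[1], d[2], d[4]))
  }
  pd_volume(out, vol$tr, rep(0, d[3]), vol$affine)
}

#' Polynomial detrending
#'
#' Fits and subtracts a least-squares polynomial of the given degree from
#' every voxel time series, removing slow scanner and physiological drift.
#'
#' @param vol A [pd_volume()].
#' @param degree Polynomial degree (default 3).
#' @return Detrended [pd_volume()]; per-voxel mean is ~0.
#' @export
detrend <- function(vol, degree = 3L) {
  stopifnot(inherits(vol, "pd_volume"))
  d <- dim(vol$values)
  if (d[4] <= degree + 1L) stop("not enough time points for the requested degree")
  tt <- seq_len(d[4])
  X <- stats::poly(tt, degree = degree, raw = FALSE)
  X <- cbind(1, X)
  H <- X %*% solve(crossprod(X), t(X))      # hat matrix, shared by all voxels
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  resid <- m - m %*% t(H)
  pd_volume(array(resid, d), vol$tr, vol$slice_onsets, vol$affine)
}

#' Global signal of a volume
#' @param vol A [pd_volume()].
#' @param mask Optional logical (x, y, z) array of in-brain voxels.
#' @return Numeric time series: the voxel-mean at every volume.
#' @export
global_signal <- function(vol, mask = NULL) {
  d <- dim(vol$values)
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  colMeans(m)
}

#' Calm-period detection from the global signal
#'
#' The global-signal (GS) baseline is first estimated by linear regression
#' over the whole scan. A rolling standard deviation of the GS is then
#' compared with `threshold_ratio` of the local baseline value: volumes where
#' it stays below are calm, and maximal calm runs of at least `min_duration`
#' seconds are kept. The calm score is the total retained duration. The rule
#' is invariant to affine rescaling of the GS (the threshold is relative).
#'
#' @param gs Global-signal time series.
#' @param tr Sampling interval, s.
#' @param threshold_ratio Allowed rolling sd as a fraction of the local
#'   baseline (default 0.05).
#' @param min_duration Minimum calm duration, s (default 60).
#' @param window Rolling-std window length, s (default 24).
#' @return Object of class `calm_segments`: data.frame `segments`
#'   (start, end half-open volume indices, 1-based start, exclusive end),
#'   `calm_score` (s), `calm` (per-volume logical), `excluded` (TRUE when
#'   the calm score is below 600 s).
#' @export
detect_calm_periods <- function(gs, tr, threshold_ratio = 0.05,
                                min_duration = 60, window = 24) {
  n <- length(gs)
  if (!all(is.finite(gs))) stop("global signal must be finite")
  empty <- list(segments = data.frame(start = integer(), end = integer()),
                calm_score = 0, calm = rep(FALSE, n), excluded = TRUE)
  class(empty) <- "calm_segments"
  if (n * tr < min_duration) return(empty)

  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), gs)
  baseline <- drop(cbind(1, tt) %*% fit$coefficients)

  half <- max(1L, floor((window / tr) / 2))
  roll_sd <- vapply(tt, function(i) {
    w <- max(1L, i - half):min(n, i + half)
    stats::sd(gs[w])
  }, numeric(1))

  calm <- roll_sd < threshold_ratio * abs(baseline)
  # keep maximal runs >= min_duration
  r <- rle(calm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * tr >= min_duration
  segs <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  calm_kept <- rep(FALSE, n)
  for (i in seq_len(nrow(segs))) {
    calm_kept[segs$start[i]:(segs$end[i] - 1L)] <- TRUE
  }
  score <- sum(calm_kept) * tr
  structure(list(segments = segs, calm_score = score, calm = calm_kept,
                 excluded = score < 600), class = "calm_segments")
}

# Zero-phase 4th-order Butterworth band-pass: forward-backward filtering, so
# the passband phase is zero and the effective order is 8.
bandpass_zero_phase <- function(x, fs, band = c(0.01, 0.1), order = 4) {
  wn <- band / (fs / 2)
  if (wn[2] >= 1) stop("upper band edge at or above Nyquist")
  bf <- signal::butter(order, wn, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Band-pass, standardize and concatenate calm periods
#'
#' Each calm segment is processed independently: every voxel series is
#' z-scored over the segment, then band-pass filtered (zero-phase Butterworth,
#' default 0.01-0.1 Hz), and the filtered segments are concatenated along
#' time. Standardize-then-filter order is deliberate and documented.
#'
#' @param vol A [pd_volume()].
#' @param segments A [detect_calm_periods()] result, or NULL to treat the
#'   whole scan as one calm segment.
#' @param band Pass band (low, high), Hz.
#' @return A [pd_volume()] of the concatenated filtered segments.
#' @export
bandpass_standardize_concat <- function(vol, segments = NULL,
                                        band = c(0.01, 0.1)) {
  stopifnot(inherits(vol, "pd_volume"))
  d <- dim(vol$values)
  if (is.null(segments)) {
    segs <- data.frame(start = 1L, end = d[4] + 1L)
  } else {
    segs <- segments$segments
  }
  if (nrow(segs) == 0L) {
    stop("no calm segments to process; scan should be excluded upstream")
  }
  fs <- 1 / vol$tr
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  pieces <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:(segs$end[i] - 1L)
    seg <- m[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    sdv <- apply(seg, 1, stats::sd)
    sdv[sdv == 0] <- 1
    seg <- (seg - mu) / sdv
    pieces[[i]] <- t(apply(seg, 1, bandpass_zero_phase, fs = fs, band = band))
  }
  out <- do.call(cbind, pieces)
  pd_volume(array(out, c(d[1:3], ncol(out))), vol$tr,
            rep(0, d[3]), vol$affine)
}

#' Global-signal regression
#'
#' Projects the brain-mean time course (plus an intercept) out of every voxel
#' series by least squares and returns the residuals; the global signal of
#' the output is ~0. Used only for awake resting-state data, where global
#' non-neuronal variance dominates.
#'
#' @param vol A [pd_volume()].
#' @param mask Optional in-brain mask for the global signal.
#' @return Residual [pd_volume()].
#' @export
global_signal_regress <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "pd_volume"))
  d <- dim(vol$values)
  gs <- global_signal(vol, mask)
  X <- cbind(1, gs)
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  H <- X %*% solve(crossprod(X), t(X))
  resid <- m - m %*% t(H)
  pd_volume(array(resid, d), vol$tr, vol$slice_onsets, vol$affine)
}

#' Full preprocessing pipeline
#'
#' Runs, in order: slice-timing correction, degree-3 polynomial detrending,
#' calm-period detection on the global signal (of the raw, pre-detrend
#' series), per-segment standardize + band-pass + concatenation, and —
#' in the awake/resting configuration — global-signal regression. Task data
#' from anesthetized animals uses `calm = FALSE, gsr = FALSE, bandpass =
#' FALSE`, leaving STC + detrending only.
#'
#' @param vol A [pd_volume()].
#' @param detrend_degree Polynomial degree for detrending.
#' @param calm Detect calm periods and restrict to them?
#' @param bandpass Apply standardize + band-pass + concatenation?
#' @param gsr Apply global-signal regression at the end?
#' @param band Pass band, Hz.
#' @param calm_threshold,calm_min_s,calm_window_s Calm-detection parameters.
#' @return List: `vol` (processed [pd_volume()]), `calm`
#'   ([detect_calm_periods()] result or NULL), `excluded` (logical).
#' @export
preprocess <- function(vol, detrend_degree = 3L, calm = TRUE,
                       bandpass = TRUE, gsr = TRUE, band = c(0.01, 0.1),
                       calm_threshold = 0.05, calm_min_s = 60,
                       calm_window_s = 24) {
  stopifnot(inherits(vol, "pd_volume"))
  v <- slice_timing_correct(vol)
  gs_raw <- global_signal(v)
  v <- detrend(v, degree = detrend_degree)
  segs <- NULL
  excluded <- FALSE
  if (calm) {
    segs <- detect_calm_periods(gs_raw, vol$tr, calm_threshold, calm_min_s,
                                calm_window_s)
    excluded <- segs$excluded
  }
  if (bandpass && !excluded) {
    v <- bandpass_standardize_concat(v, segs, band = band)
  }
  if (gsr && !excluded) {
    v <- global_signal_regress(v)
  }
  list(vol = v, calm = segs, excluded = excluded)
}
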