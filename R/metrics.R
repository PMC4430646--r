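# Curve post-processing and agreement statistics: zero-phase Butterworth
# filtering, time normalization to the gait cycle, RMSD, MAE/MAE%, and the
# linear-fit waveform-similarity method (shape R^2, amplitude A0, offset A1).

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order low-pass Butterworth (default cut-off 10 Hz) applied
#' forward and backward for zero phase lag. The series is extended at both
#' ends by odd (point-mirrored) reflection of length 3 x order before
#' filtering to suppress end transients.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param cutoff cut-off frequency, Hz.
#' @param order filter order.
#' @return filtered series, same length.
#' @export
lowpass_filter <- function(x, fs, cutoff = 10, order = 4) {
  stopifnot(fs > 2 * cutoff)
  n <- length(x)
  pad <- 3 * order
  if (n < pad + 1)
    gait2d_stop("gait2d_series_too_short",
                sprintf("series of length %d too short for order-%d filtering", n, order))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  # offset by the leading sample before filtering so that the zero initial
  # state of the recursion introduces no step transient (DC gain is 1)
  filt0 <- function(v) {
    as.numeric(signal::filter(bf, v - v[1])) + v[1]
  }
  fwd <- filt0(ext)
  bwd <- rev(filt0(rev(fwd)))
  bwd[(pad + 1):(pad + n)]
}

#' Time-normalize a series to the gait cycle
#'
#' Linear interpolation of the per-frame series onto `n_points` evenly
#' spaced samples spanning the cycle (0 to 100% inclusive); endpoints are
#' preserved exactly.
#'
#' @param x per-frame series.
#' @param start,end cycle start/end positions in frame units (may be
#'   fractional); `x[k]` is the value at frame position `k`.
#' @param n_points number of output samples (101 = every 1% of the cycle).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, start, end, n_points = 101) {
  if (end <= start)
    gait2d_stop("gait2d_bad_cycle", "cycle end must be after its start")
  if (start < 1 || end > length(x))
    gait2d_stop("gait2d_bad_cycle", "cycle extends beyond the series")
  approx(seq_along(x), x, xout = seq(start, end, length.out = n_points))$y
}

#' Root-mean-square deviation between two curves
#'
#' @param a,b equal-length numeric curves (deg).
#' @return RMSD in the curves' units.
#' @export
rmsd <- function(a, b) {
  if (length(a) != length(b))
    gait2d_stop("gait2d_length_mismatch", "curves must have equal length")
  sqrt(mean((a - b)^2))
}

#' Linear-fit waveform similarity
#'
#' Regresses the estimated curve on the reference curve
#' (`estimated = A0 * reference + A1`). The slope A0 measures amplitude
#' agreement, the intercept A1 the offset, and the coefficient of
#' determination R^2 the shape similarity.
#'
#' @param estimated,reference equal-length curves (reference on the
#'   abscissa).
#' @return list with `R2`, `A0`, `A1`.
#' @export
linear_fit_similarity <- function(estimated, reference) {
  if (length(estimated) != length(reference))
    gait2d_stop("gait2d_length_mismatch", "curves must have equal length")
  if (length(estimated) < 3)
    gait2d_stop("gait2d_series_too_short", "need at least 3 samples")
  if (var(reference) < 1e-12)
    gait2d_stop("gait2d_degenerate_reference",
                "constant reference curve: slope undefined")
  A0 <- cov(estimated, reference) / var(reference)
  A1 <- mean(estimated) - A0 * mean(reference)
  pred <- A0 * reference + A1
  sst <- sum((estimated - mean(estimated))^2)
  sse <- sum((estimated - pred)^2)
  R2 <- if (sst < 1e-24) as.numeric(sse < 1e-24) else 1 - sse / sst
  list(R2 = R2, A0 = A0, A1 = A1)
}

#' Mean absolute error and percentage error
#'
#' @param estimates,references equal-length numeric vectors (e.g. one
#'   value per trial).
#' @return list with `MAE` and `MAE_pct` (percentage of the mean reference
#'   value; `NA` with a warning attribute when the reference mean is zero).
#' @export
mae <- function(estimates, references) {
  if (length(estimates) != length(references) || !length(estimates))
    gait2d_stop("gait2d_length_mismatch",
                "estimates and references must have equal positive length")
  m <- mean(abs(estimates - references))
  denom <- mean(references)
  if (abs(denom) < 1e-12)
    return(list(MAE = m, MAE_pct = NA_real_, flag = "zero-mean reference"))
  list(MAE = m, MAE_pct = 100 * m / denom)
}

#' Compare an estimated kinematic curve against a reference
#'
#' Convenience wrapper computing RMSD and the linear-fit statistics for a
#' pair of time-normalized curves.
#'
#' @param estimated,reference 101-sample curves, deg.
#' @return list with `RMSD`, `R2`, `A0`, `A1`.
#' @export
compare_curves <- function(estimated, reference) {
  lf <- linear_fit_similarity(estimated, reference)
  list(RMSD = rmsd(estimated, reference), R2 = lf$R2, A0 = lf$A0, A1 = lf$A1)
}
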