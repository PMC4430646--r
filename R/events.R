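# Gait event detection from pelvis and foot centroid trajectories, and
# spatiotemporal parameter computation.

# local maxima of a series: strictly greater than the previous value,
# plateaus resolved to their first frame; interior extrema only.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_peak <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  starts[mid][is_peak]
}

# topographic prominence of peaks in a series (equal-height plateau
# samples do not terminate the base search)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    base_l <- if (p > 1) {
      left <- x[(p - 1):1]                 # outward from the peak
      higher <- which(left > h)
      min(left[seq_len(if (length(higher)) min(higher) else length(left))])
    } else min(x)
    base_r <- if (p < length(x)) {
      right <- x[(p + 1):length(x)]
      higher <- which(right > h)
      min(right[seq_len(if (length(higher)) min(higher) else length(right))])
    } else min(x)
    h - max(base_l, base_r)
  }, numeric(1))
}

# peaks filtered by prominence and minimum separation (greedy by height)
find_peaks <- function(x, min_prominence = 0, min_separation = 0) {
  p <- local_maxima(x)
  if (!length(p)) return(integer(0))
  if (min_prominence > 0) p <- p[peak_prominence(x, p) >= min_prominence]
  if (min_separation > 0 && length(p) > 1) {
    keep <- logical(length(p))
    for (i in order(x[p], decreasing = TRUE)) {
      if (!any(keep & abs(p - p[i]) < min_separation)) keep[i] <- TRUE
    }
    p <- sort(p[keep])
  }
  sort(p)
}

#' Detect heel-strike and toe-off events from centroid trajectories
#'
#' The gait events are located where the horizontal distance between the
#' foot and pelvis centroids is extremal: heel strikes at the local maxima
#' (foot maximally forward of the pelvis), toe offs at the local minima.
#' A minimum prominence and a minimum separation (relative to the median
#' inter-peak spacing) debounce jitter; plateau extrema resolve to their
#' first frame.
#'
#' @param pelvis_x,foot_x equal-length per-frame horizontal centroid
#'   coordinates, px (gaps pre-interpolated).
#' @param fps frame rate.
#' @param side label attached to the events (`"foreground"` or
#'   `"background"`).
#' @param min_prominence minimum peak prominence, px.
#' @param min_separation_frac minimum event separation as a fraction of
#'   the median same-type event spacing.
#' @return object of class `gait_events`: list with `heel_strikes`,
#'   `toe_offs` (frame indices), `cycles` (two-column matrix of
#'   consecutive ipsilateral heel-strike pairs), `side`, `fps`.
#' @export
detect_gait_events <- function(pelvis_x, foot_x, fps, side = "foreground",
                               min_prominence = 10,
                               min_separation_frac = 0.4) {
  stopifnot(length(pelvis_x) == length(foot_x), length(foot_x) >= 3)
  d <- foot_x - pelvis_x
  if (max(d) - min(d) < 1e-9)
    gait2d_stop("gait2d_no_events",
                "constant pelvis-foot distance: no gait events detectable")
  sep_from <- function(p) {
    if (length(p) < 2) return(0)
    min_separation_frac * median(diff(p))
  }
  hs0 <- find_peaks(d, min_prominence)
  hs <- find_peaks(d, min_prominence, sep_from(hs0))
  to0 <- find_peaks(-d, min_prominence)
  to <- find_peaks(-d, min_prominence, sep_from(to0))
  if (!length(hs) && !length(to))
    gait2d_stop("gait2d_no_events", "no extrema of the pelvis-foot distance found")
  cycles <- if (length(hs) >= 2) cbind(start = hs[-length(hs)], end = hs[-1])
            else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  structure(list(heel_strikes = hs, toe_offs = to, cycles = cycles,
                 side = side, fps = fps),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> (%s leg) HS: %s | TO: %s\n", x$side,
              paste(x$heel_strikes, collapse = ", "),
              paste(x$toe_offs, collapse = ", ")))
  invisible(x)
}

#' Spatiotemporal gait parameters from detected events
#'
#' For each gait cycle (consecutive ipsilateral heel strikes): stride time
#' from the frame difference, stride length from the foot-centroid advance
#' converted to metres, cadence assuming two steps per stride, and walking
#' speed as stride length over stride time. Multi-cycle trials report
#' per-cycle values and their means.
#'
#' @param events a [detect_gait_events()] result with >= 2 heel strikes.
#' @param foot_x per-frame foot centroid horizontal coordinate, px.
#' @param mm_per_px spatial scale.
#' @param fps frame rate.
#' @return object of class `spatiotemporal_params`: list with `cadence`
#'   (steps/min), `walking_speed` (m/s), `stride_time` (s), `stride_length`
#'   (m) and a per-cycle data.frame `per_cycle`.
#' @export
spatiotemporal_params <- function(events, foot_x, mm_per_px, fps) {
  if (nrow(events$cycles) < 1)
    gait2d_stop("gait2d_no_events",
                "need at least 2 ipsilateral heel strikes for gait parameters")
  per <- apply(events$cycles, 1, function(cy) {
    st <- (cy[2] - cy[1]) / fps
    sl <- abs(foot_x[cy[2]] - foot_x[cy[1]]) * mm_per_px / 1000
    c(stride_time = st, stride_length = sl,
      cadence = 120 / st, walking_speed = sl / st)
  })
  per <- as.data.frame(t(per))
  structure(list(cadence = mean(per$cadence),
                 walking_speed = mean(per$walking_speed),
                 stride_time = mean(per$stride_time),
                 stride_length = mean(per$stride_length),
                 per_cycle = per),
            class = "spatiotemporal_params")
}

#' @export
print.spatiotemporal_params <- function(x, ...) {
  cat(sprintf(paste0("<spatiotemporal_params> cadence %.1f steps/min, ",
                     "speed %.3f m/s, stride time %.3f s, stride length %.3f m\n"),
              x$cadence, x$walking_speed, x$stride_time, x$stride_length))
  invisible(x)
}
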