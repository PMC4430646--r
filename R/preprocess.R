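# Image preprocessing: lens undistortion, pixel/mm scaling, HSV background
# subtraction, white-garment extraction, segmental-marker labelling and
# contour extraction.

#' Radial-tangential lens distortion coefficients
#'
#' @param k1,k2 radial coefficients.
#' @param p1,p2 tangential coefficients.
#' @param center optical centre `c(cx, cy)` in px; defaults to the image
#'   centre when applied to a frame.
#' @param focal focal length in px used to normalize coordinates.
#' @return object of class `distortion_coeffs`.
#' @export
distortion_coeffs <- function(k1 = 0, k2 = 0, p1 = 0, p2 = 0,
                              center = NULL, focal = 1000) {
  structure(list(k1 = k1, k2 = k2, p1 = p1, p2 = p2,
                 center = center, focal = focal),
            class = "distortion_coeffs")
}

# forward model: ideal -> distorted (points, px)
distort_points <- function(pts, coeffs) {
  ctr <- coeffs$center; f <- coeffs$focal
  xn <- (pts[, 1] - ctr[1]) / f; yn <- (pts[, 2] - ctr[2]) / f
  r2 <- xn^2 + yn^2
  rad <- 1 + coeffs$k1 * r2 + coeffs$k2 * r2^2
  xd <- xn * rad + 2 * coeffs$p1 * xn * yn + coeffs$p2 * (r2 + 2 * xn^2)
  yd <- yn * rad + coeffs$p1 * (r2 + 2 * yn^2) + 2 * coeffs$p2 * xn * yn
  cbind(xd * f + ctr[1], yd * f + ctr[2])
}

#' Undistort pixel coordinates
#'
#' Inverts the standard radial-tangential distortion model by fixed-point
#' iteration. With all coefficients zero this is the identity.
#'
#' @param pts n x 2 matrix of distorted pixel coordinates.
#' @param coeffs a [distortion_coeffs()] (with `center` set).
#' @param iterations fixed-point iterations.
#' @return n x 2 matrix of undistorted coordinates.
#' @export
undistort_points <- function(pts, coeffs, iterations = 20) {
  ctr <- coeffs$center; f <- coeffs$focal
  xd <- (pts[, 1] - ctr[1]) / f; yd <- (pts[, 2] - ctr[2]) / f
  xn <- xd; yn <- yd
  for (it in seq_len(iterations)) {
    r2 <- xn^2 + yn^2
    rad <- 1 + coeffs$k1 * r2 + coeffs$k2 * r2^2
    dx <- 2 * coeffs$p1 * xn * yn + coeffs$p2 * (r2 + 2 * xn^2)
    dy <- coeffs$p1 * (r2 + 2 * yn^2) + 2 * coeffs$p2 * xn * yn
    xn <- (xd - dx) / rad
    yn <- (yd - dy) / rad
  }
  cbind(xn * f + ctr[1], yn * f + ctr[2])
}

#' Undistort a frame
#'
#' Resamples the frame so that straight world lines become straight image
#' lines. `coeffs = NULL` (pass-through) or all-zero coefficients return
#' the input unchanged.
#'
#' @param rgb width x height x 3 array.
#' @param coeffs a [distortion_coeffs()] or `NULL`.
#' @return undistorted array, same shape.
#' @export
undistort_frame <- function(rgb, coeffs = NULL) {
  if (is.null(coeffs)) return(rgb)
  if (coeffs$k1 == 0 && coeffs$k2 == 0 && coeffs$p1 == 0 && coeffs$p2 == 0)
    return(rgb)
  W <- dim(rgb)[1]; H <- dim(rgb)[2]
  if (is.null(coeffs$center)) coeffs$center <- c((W + 1) / 2, (H + 1) / 2)
  grid <- cbind(rep(seq_len(W), H), rep(seq_len(H), each = W))
  src <- distort_points(grid, coeffs)
  x0 <- pmin(pmax(floor(src[, 1]), 1), W - 1); fx <- src[, 1] - x0
  y0 <- pmin(pmax(floor(src[, 2]), 1), H - 1); fy <- src[, 2] - y0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  out <- rgb
  for (c in 1:3) {
    pl <- rgb[, , c]
    v <- pl[i00] * (1 - fx) * (1 - fy) + pl[i10] * fx * (1 - fy) +
      pl[i01] * (1 - fx) * fy + pl[i11] * fx * fy
    out[, , c] <- matrix(v, W, H)
  }
  out
}

#' Pixel-to-mm scale from the static foot marker
#'
#' Associates the measured foot length with the horizontal pixel extent of
#' the foot segmental marker in the static reference image.
#'
#' @param foot_length_mm measured foot length, mm.
#' @param foot_marker a garment-marker blob (needs `$contour`).
#' @return mm per pixel (scalar).
#' @export
compute_scale <- function(foot_length_mm, foot_marker) {
  stopifnot(foot_length_mm > 0)
  # pixel-count extent: number of columns spanned by the marker
  ext <- diff(range(foot_marker$contour[, 1])) + 1
  if (ext <= 1)
    gait2d_stop("gait2d_degenerate_marker",
                "foot marker has zero horizontal extent")
  foot_length_mm / ext
}

#' Background model for HSV background subtraction
#'
#' Per-pixel HSV reference statistics from one or more subject-free frames
#' of the homogeneous background, with per-channel tolerances.
#'
#' @param frames an RGB array or list of RGB arrays.
#' @param h_tol_deg hue tolerance, degrees.
#' @param s_tol,v_tol saturation / value tolerances.
#' @return object of class `background_model`.
#' @export
background_model <- function(frames, h_tol_deg = 10, s_tol = 0.25,
                             v_tol = 0.25) {
  stopifnot(h_tol_deg >= 0, s_tol >= 0, v_tol >= 0)
  if (!is.list(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  # circular mean for hue
  cs <- sn <- s <- v <- matrix(0, d[1], d[2])
  for (f in frames) {
    hv <- frame_hsv(f)
    cs <- cs + cos(hv$h_deg * pi / 180); sn <- sn + sin(hv$h_deg * pi / 180)
    s <- s + hv$s; v <- v + hv$v
  }
  n <- length(frames)
  structure(list(h_deg = (atan2(sn, cs) * 180 / pi) %% 360,
                 s = s / n, v = v / n,
                 h_tol_deg = h_tol_deg, s_tol = s_tol, v_tol = v_tol,
                 dim = d[1:2]),
            class = "background_model")
}

#' Segment the subject silhouette from a frame
#'
#' A pixel is foreground when its HSV value departs from the background
#' statistics beyond tolerance on any channel; the largest connected
#' component (holes filled) is retained as the subject.
#'
#' @param rgb width x height x 3 frame.
#' @param bg a [background_model()] of the same dimensions.
#' @param roi optional `c(x0, x1, y0, y1)` window hint restricting the
#'   search (used by the pipeline to track the subject's bounding box).
#' @param clean apply a morphological open/close cleanup to the mask.
#'   Used for the static reference image, where single-pixel boundary
#'   noise would bias the calibration; dynamic frames are left raw so
#'   that closely spaced leg contours are never bridged.
#' @return object of class `silhouette`: list with `mask` (integer matrix),
#'   `contour` (ordered outer boundary, n x 2 px), `area`, `bbox`.
#' @export
segment_foreground <- function(rgb, bg, roi = NULL, clean = FALSE) {
  stopifnot(inherits(bg, "background_model"),
            all(dim(rgb)[1:2] == bg$dim))
  W <- dim(rgb)[1]; H <- dim(rgb)[2]
  if (is.null(roi)) roi <- c(1, W, 1, H)
  xs <- roi[1]:roi[2]; ys <- roi[3]:roi[4]
  hv <- frame_hsv(rgb[xs, ys, , drop = FALSE])
  dh <- abs(hv$h_deg - bg$h_deg[xs, ys])
  dh <- pmin(dh, 360 - dh)
  fg_roi <- dh > bg$h_tol_deg | abs(hv$s - bg$s[xs, ys]) > bg$s_tol |
    abs(hv$v - bg$v[xs, ys]) > bg$v_tol
  mask <- matrix(FALSE, W, H)
  mask[xs, ys] <- fg_roi
  if (!any(mask))
    gait2d_stop("gait2d_no_subject", "no foreground pixels: no subject in frame")
  lab <- EBImage::bwlabel(mask * 1L)
  counts <- tabulate(lab[lab > 0])
  id <- which.max(counts)
  m <- EBImage::fillHull((lab == id) * 1L)
  if (clean) {
    kern <- EBImage::makeBrush(3, "box")
    m <- EBImage::opening(EBImage::closing(m, kern), kern)
  }
  m <- matrix(as.integer(m > 0), W, H)
  ij <- which(m > 0, arr.ind = TRUE)
  structure(list(mask = m,
                 contour = extract_contour(m),
                 area = nrow(ij),
                 bbox = c(range(ij[, 1]), range(ij[, 2]))),
            class = "silhouette")
}

#' Ordered outer contour of a binary mask
#'
#' Traces the closed outer boundary of the largest object in the mask
#' (inner hole boundaries are ignored).
#'
#' @param mask integer/logical matrix (width x height).
#' @return n x 2 matrix of ordered boundary pixel coordinates (x, y),
#'   1-based.
#' @export
extract_contour <- function(mask) {
  if (!any(mask > 0))
    gait2d_stop("gait2d_empty_mask", "cannot trace the contour of an empty mask")
  lab <- EBImage::bwlabel(mask * 1L)
  counts <- tabulate(lab[lab > 0])
  id <- which.max(counts)
  oc <- EBImage::ocontour(lab)[[id]]
  unname(oc + 1L)
}

#' Extract white garment markers from a frame
#'
#' White blobs are foreground pixels with low saturation and high value;
#' connected components above a minimum area are returned (unlabelled).
#'
#' @param rgb frame.
#' @param silhouette a [segment_foreground()] result.
#' @param s_max,v_min white-filter thresholds.
#' @param min_area minimum blob area, px^2.
#' @param clean morphological open/close cleanup (static image only, see
#'   [segment_foreground()]).
#' @return list of blobs, each with `pixels` (n x 2), `centroid`, `area`,
#'   `contour`, `bbox`.
#' @export
extract_garment_markers <- function(rgb, silhouette, s_max = 0.2,
                                    v_min = 0.8, min_area = 50,
                                    clean = FALSE) {
  W <- dim(rgb)[1]; H <- dim(rgb)[2]
  bb <- silhouette$bbox
  xs <- bb[1]:bb[2]; ys <- bb[3]:bb[4]
  hv <- frame_hsv(rgb[xs, ys, , drop = FALSE])
  white <- matrix(FALSE, W, H)
  white[xs, ys] <- hv$s < s_max & hv$v > v_min
  white <- white & silhouette$mask > 0
  if (clean) {
    kern <- EBImage::makeBrush(3, "box")
    white <- EBImage::opening(EBImage::closing(white * 1L, kern), kern) > 0
  }
  if (!any(white))
    gait2d_stop("gait2d_no_markers", "no white garment pixels inside silhouette")
  lab <- EBImage::bwlabel(white * 1L)
  counts <- tabulate(lab[lab > 0])
  ids <- which(counts >= min_area)
  if (!length(ids))
    gait2d_stop("gait2d_no_markers",
                sprintf("no white blob reaches the minimum area (%d px^2)", min_area))
  oc <- EBImage::ocontour(lab)
  lapply(ids, function(id) {
    ij <- which(lab == id, arr.ind = TRUE)
    list(pixels = unname(ij),
         centroid = c(mean(ij[, 1]), mean(ij[, 2])),
         area = nrow(ij),
         contour = unname(oc[[id]] + 1L),
         bbox = c(range(ij[, 1]), range(ij[, 2])))
  })
}

#' Label garment blobs as pelvis / foreground foot / background foot
#'
#' The pelvis marker is the white blob with the highest centroid; each foot
#' is assigned to the blob nearest its constant-velocity predicted centroid
#' from the previous two labelled frames. On the first frames (no history)
#' the foreground foot is the most advanced (largest x) foot blob. When a
#' single foot blob lies under both predictions the feet are flagged as
#' merged and share the blob.
#'
#' @param blobs list from [extract_garment_markers()].
#' @param state a [foot_tracker_state()] holding each foot's last two
#'   unmerged observations (or `NULL` at cold start). Predictions coast at
#'   constant velocity through merged-marker frames, so the feet keep
#'   their identities across a crossing.
#' @param frame frame index of `blobs` (used to extrapolate the state).
#' @return list with `pelvis`, `foot_fg`, `foot_bg` blobs, logical
#'   `merged`, and a character vector `warnings`.
#' @export
label_markers <- function(blobs, state = NULL, frame = NA_real_) {
  if (!length(blobs))
    gait2d_stop("gait2d_no_markers", "no blobs to label")
  warnings <- character(0)
  cy <- vapply(blobs, function(b) b$centroid[2], numeric(1))
  pelvis <- blobs[[which.max(cy)]]
  feet <- blobs[-which.max(cy)]
  if (!length(feet))
    gait2d_stop("gait2d_no_markers", "no foot blobs found")
  p_fg <- predict_foot(state$fg, frame)
  p_bg <- predict_foot(state$bg, frame)
  merged <- FALSE
  if (length(feet) == 1) {
    foot_fg <- foot_bg <- feet[[1]]
    merged <- !is.null(p_fg)  # with history, one blob serving two feet
  } else {
    # keep the two largest candidates
    ord <- order(vapply(feet, `[[`, numeric(1), "area"), decreasing = TRUE)
    feet <- feet[ord[1:2]]
    cx <- vapply(feet, function(b) b$centroid[1], numeric(1))
    if (is.null(p_fg)) {           # initialization rule: x-order
      foot_fg <- feet[[which.max(cx)]]
      foot_bg <- feet[[which.min(cx)]]
    } else {                        # nearest-prediction assignment
      d <- function(b, p) sqrt(sum((b$centroid - p)^2))
      c1 <- d(feet[[1]], p_fg) + d(feet[[2]], p_bg)
      c2 <- d(feet[[2]], p_fg) + d(feet[[1]], p_bg)
      if (c1 <= c2) { foot_fg <- feet[[1]]; foot_bg <- feet[[2]] }
      else          { foot_fg <- feet[[2]]; foot_bg <- feet[[1]] }
    }
  }
  # the pelvis blob should sit above the feet; compare against the
  # predicted foot heights (the blob heights cannot contradict the rule
  # by construction, the predictions can)
  if (!is.null(p_fg) &&
      pelvis$centroid[2] < max(p_fg[2], p_bg[2]))
    warnings <- c(warnings, "pelvis blob below a predicted foot: labelling inconsistent")
  list(pelvis = pelvis, foot_fg = foot_fg, foot_bg = foot_bg,
       merged = merged, warnings = warnings)
}

#' Foot-marker tracker state
#'
#' Holds, per foot, the frames and centroids of the last two unmerged
#' labellings, from which [label_markers()] extrapolates predicted
#' centroid positions at constant velocity.
#'
#' @return empty state (list with `fg`, `bg` slots).
#' @export
foot_tracker_state <- function() list(fg = NULL, bg = NULL)

# constant-velocity extrapolation of a foot track to frame `frame`
predict_foot <- function(side, frame) {
  if (is.null(side) || !length(side$frames)) return(NULL)
  k <- length(side$frames)
  if (k == 1 || is.na(frame)) return(side$cents[k, ])
  v <- (side$cents[k, ] - side$cents[k - 1, ]) /
    (side$frames[k] - side$frames[k - 1])
  side$cents[k, ] + v * (frame - side$frames[k])
}

#' Update the foot tracker state with a labelling result
#'
#' Merged-marker frames are not recorded, so that predictions keep using
#' the last clean per-foot velocities while the socks overlap.
#'
#' @param state a [foot_tracker_state()].
#' @param labelled a [label_markers()] result.
#' @param frame frame index of the labelling.
#' @return updated state.
#' @export
update_foot_state <- function(state, labelled, frame) {
  if (isTRUE(labelled$merged)) return(state)
  push <- function(side, cent) {
    if (is.null(side)) side <- list(frames = numeric(0),
                                    cents = matrix(numeric(0), 0, 2))
    side$frames <- c(side$frames, frame)
    side$cents <- rbind(side$cents, cent)
    k <- length(side$frames)
    if (k > 2) { side$frames <- side$frames[(k - 1):k]
                 side$cents <- side$cents[(k - 1):k, , drop = FALSE] }
    side
  }
  state$fg <- push(state$fg, labelled$foot_fg$centroid)
  state$bg <- push(state$bg, labelled$foot_bg$centroid)
  state
}
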