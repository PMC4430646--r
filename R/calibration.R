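# Subject-specific model calibration from the static reference image:
# foot contour template and anatomical axes, tibia/femur reference-point
# templates from circle-contour intersections, and the pelvis double
# calibration anchoring the lateral point PL to the automatically
# detectable posterior point PP at the first and last cycle frames.

# PCA (total least squares) line fit anchored to the lowest contour band
# (the flat plantar edge), grown by iterative inlier re-selection so that
# the posterior vertical edge and heel curve do not bias the axis.
# Returns list(angle_deg, point, n_inliers). Angle in (-90, 90].
fit_line_robust <- function(pts, inlier_tol = 1.5, rounds = 5, seed_band = 3) {
  pca <- function(p) {
    ctr <- colMeans(p)
    v <- svd(sweep(p, 2, ctr))$v
    list(ctr = ctr, dir = v[, 1], nrm = v[, 2])
  }
  keep <- pts[, 2] <= min(pts[, 2]) + seed_band
  if (sum(keep) < 2) keep <- rep(TRUE, nrow(pts))
  fit <- pca(pts[keep, , drop = FALSE])
  for (r in seq_len(rounds)) {
    res <- abs(sweep(pts, 2, fit$ctr) %*% fit$nrm)
    new_keep <- as.vector(res) <= inlier_tol
    if (sum(new_keep) < 3 || all(new_keep == keep)) break
    keep <- new_keep
    fit <- pca(pts[keep, , drop = FALSE])
  }
  dir <- fit$dir
  if (dir[1] < 0) dir <- -dir           # orient towards +x (the toes)
  list(angle_deg = atan2(dir[2], dir[1]) * 180 / pi,
       point = fit$ctr, n_inliers = sum(keep))
}

#' Calibrate the foot model from the static image
#'
#' The foot template is the posterior half of the foot segmental-marker
#' contour. The anatomical frame CS_A has its x-axis along the line
#' fitting the lower-posterior contour (oriented towards the toes) and its
#' origin at the most posterior contour point; the technical frame CS_T is
#' axis-aligned with the image and centred in LM.
#'
#' @param foot_marker static foot blob (from [extract_garment_markers()]).
#' @param LM lateral malleolus position `c(x, y)` in px (operator click).
#' @return object of class `foot_model`: `template` (n x 2, CS_T
#'   coordinates), `T_A_from_T` ([tf2d()] mapping CS_T -> CS_A), `LM`
#'   (static px), plus the static marker contour.
#' @export
calibrate_foot <- function(foot_marker, LM) {
  ct <- foot_marker$contour
  xr <- range(ct[, 1]); yr <- range(ct[, 2])
  xmid <- mean(xr)
  template_I <- ct[ct[, 1] <= xmid, , drop = FALSE]
  # lower-posterior contour: posterior half, below the vertical midline,
  # robustly re-fit so the flat plantar edge dominates
  low <- template_I[template_I[, 2] < mean(yr), , drop = FALSE]
  if (nrow(low) < 3)
    gait2d_stop("gait2d_degenerate_contour",
                "fewer than 3 lower-posterior contour points for the foot axis fit")
  fit <- fit_line_robust(low)
  # origin at most posterior point, ties broken by lowest y
  cand <- ct[ct[, 1] == min(ct[, 1]), , drop = FALSE]
  origin_I <- cand[which.min(cand[, 2]), ]
  # CS_T: axes parallel to CS_I, origin at LM
  template_T <- sweep(template_I, 2, LM)
  # T maps CS_T coords -> CS_A coords
  a <- -fit$angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t_at <- as.vector(R %*% (LM - origin_I))
  structure(list(template = template_T,
                 T_A_from_T = tf2d(-fit$angle_deg, t_at[1], t_at[2]),
                 LM = LM, origin_A = origin_I,
                 axis_angle_deg = fit$angle_deg,
                 cut_T = xmid - LM[1],   # posterior-half cut along the foot
                 contour = ct),
            class = "foot_model")
}

#' Calibrate a long segment (tibia or femur) from the static silhouette
#'
#' Reference points are the intersections between the silhouette contour
#' and circles centred in the proximal ("center") landmark, with radii
#' evenly spaced in the middle portion of the segment (avoiding the
#' joint-adjacent zones with larger soft-tissue deformation). Each circle
#' contributes the two contour intersections, one per side of the segment
#' axis. The technical frame CS_T is axis-aligned with the image and
#' centred in the centroid of the reference points; the anatomical frame
#' CS_A has its y-axis joining the center and distal landmarks, origin at
#' the center landmark.
#'
#' @param contour static silhouette contour (n x 2 px).
#' @param center,distal landmark positions in px (LM and LE for the tibia;
#'   LE and GT for the femur).
#' @param n_points number of reference points (10 tibia, 6 femur; must be
#'   even).
#' @param band radial band as fractions of the segment length.
#' @param tol maximum | |p - center| - r | for a contour point to count as
#'   a circle intersection, px.
#' @return object of class `long_segment_model`: `template` (n x 2, CS_T),
#'   `radii`, `T_A_from_T`, `center_T`, `distal_T`, static landmark
#'   positions.
#' @export
calibrate_long_segment <- function(contour, center, distal, n_points = 10,
                                   band = c(0.25, 0.75), tol = 2.5) {
  stopifnot(n_points %% 2 == 0, n_points >= 2)
  L <- sqrt(sum((distal - center)^2))
  n_circ <- n_points / 2
  radii <- (band[1] + (seq_len(n_circ) - 0.5) / n_circ * diff(band)) * L
  axis <- (distal - center) / L
  rel <- sweep(contour, 2, center)
  dist_c <- sqrt(rowSums(rel^2))
  side <- sign(rel[, 1] * axis[2] - rel[, 2] * axis[1])
  pts <- matrix(NA_real_, 0, 2); rad_idx <- integer(0)
  for (k in seq_len(n_circ)) {
    for (s in c(-1, 1)) {
      cand <- which(side == s)
      if (!length(cand))
        gait2d_stop("gait2d_calibration_failed",
                    "circle-contour intersection missing on the static image")
      err <- abs(dist_c[cand] - radii[k])
      j <- cand[which.min(err)]
      if (min(err) > tol)
        gait2d_stop("gait2d_calibration_failed",
                    sprintf("circle r=%.1f px has no contour intersection (err %.1f px)",
                            radii[k], min(err)))
      pts <- rbind(pts, contour[j, ]); rad_idx <- c(rad_idx, k)
    }
  }
  o_T <- colMeans(pts)                   # CS_T origin = centroid of points
  template <- sweep(pts, 2, o_T)
  # CS_A: y-axis along center -> distal, origin at center
  alpha <- atan2(-axis[1], axis[2]) * 180 / pi   # rotation of CS_A wrt CS_I
  a <- -alpha * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t_at <- as.vector(R %*% (o_T - center))
  structure(list(template = template,
                 radii = radii[rad_idx],
                 radii_unique = radii,
                 n_points = n_points,
                 T_A_from_T = tf2d(-alpha, t_at[1], t_at[2]),
                 center_T = as.vector(center - o_T),
                 distal_T = as.vector(distal - o_T),
                 center_I = center, distal_I = distal,
                 origin_T_I = o_T),
            class = "long_segment_model")
}

#' Pelvis double calibration
#'
#' At the first and last frames of the gait cycle the operator identifies
#' the lateral point PL while the posterior point PP of the pelvis-marker
#' upper contour is detected automatically. The horizontal PL-PP distance
#' is then interpolated linearly in between: `d_x(i) = d_x_first + Delta i`
#' with `Delta = (d_x_last - d_x_first) / M`.
#'
#' @param PL_first,PP_first,PL_last,PP_last point coordinates, px.
#' @param M number of frames spanned by the cycle (last - first).
#' @return object of class `pelvis_calibration` with `d_x_first`,
#'   `d_x_last`, `delta`, `M` and accessor-friendly fields.
#' @export
double_calibrate_pelvis <- function(PL_first, PP_first, PL_last, PP_last, M) {
  if (M < 1)
    gait2d_stop("gait2d_bad_calibration", "pelvis calibration needs M >= 1 frames")
  d_first <- PL_first[1] - PP_first[1]
  d_last <- PL_last[1] - PP_last[1]
  structure(list(d_x_first = d_first, d_x_last = d_last,
                 delta = (d_last - d_first) / M, M = M),
            class = "pelvis_calibration")
}

#' Interpolated PL-PP horizontal distance at a cycle frame
#' @param calib a [double_calibrate_pelvis()] result.
#' @param i frame index within the cycle, `0 <= i <= M` (0 = first frame).
#' @return distance in px.
#' @export
pelvis_dx <- function(calib, i) calib$d_x_first + calib$delta * i

#' Pelvis anatomical axis from the marker upper contour
#'
#' Least-squares line through the upper-contour points within a horizontal
#' window around PL, signed towards the direction of progression. The
#' signed angle of this axis to the horizontal is the pelvic tilt.
#'
#' @param upper n x 2 matrix of upper-contour points (one topmost pixel per
#'   column).
#' @param PL pelvis lateral point `c(x, y)` px.
#' @param halfwidth window halfwidth, px.
#' @return list with `tilt_deg`, `partial` (TRUE when the window is
#'   clipped), `n_points`.
#' @export
pelvis_axis_from_contour <- function(upper, PL, halfwidth = 20) {
  sel <- abs(upper[, 1] - PL[1]) <= halfwidth
  pts <- upper[sel, , drop = FALSE]
  if (nrow(pts) < 3)
    gait2d_stop("gait2d_degenerate_contour",
                "fewer than 3 upper-contour points in the PL window")
  co <- coef(lm(pts[, 2] ~ pts[, 1]))
  partial <- min(pts[, 1]) > PL[1] - halfwidth + 1 ||
    max(pts[, 1]) < PL[1] + halfwidth - 1
  list(tilt_deg = atan(co[[2]]) * 180 / pi, partial = partial,
       n_points = nrow(pts))
}

# Upper contour of a blob: topmost pixel per column.
marker_upper_contour <- function(blob) {
  px <- blob$pixels
  ymax <- tapply(px[, 2], px[, 1], max)
  cbind(x = as.numeric(names(ymax)), y = as.numeric(ymax))
}

# Most posterior point of an upper contour (min x; ties by lowest y).
most_posterior_point <- function(upper) {
  cand <- upper[upper[, 1] == min(upper[, 1]), , drop = FALSE]
  cand[which.min(cand[, 2]), ]
}

#' Calibrate the full body model from the static reference image
#'
#' @param static_rgb static reference frame.
#' @param bg a [background_model()].
#' @param landmarks list with `LM`, `LE`, `GT` positions (px) and
#'   `foot_length_mm`.
#' @param thresholds optional list overriding white-filter thresholds
#'   (`s_max`, `v_min`, `min_area`).
#' @return object of class `body_model` with `foot`, `tibia`, `femur`
#'   models, `mm_per_px`, `landmarks`, and the static silhouette.
#' @export
calibrate_body <- function(static_rgb, bg, landmarks, thresholds = list()) {
  th <- modifyList(list(s_max = 0.2, v_min = 0.8, min_area = 50), thresholds)
  sil <- segment_foreground(static_rgb, bg, clean = TRUE)
  blobs <- extract_garment_markers(static_rgb, sil, s_max = th$s_max,
                                   v_min = th$v_min, min_area = th$min_area,
                                   clean = TRUE)
  lab <- label_markers(blobs)
  foot <- calibrate_foot(lab$foot_fg, landmarks$LM)
  tibia <- calibrate_long_segment(sil$contour, landmarks$LM, landmarks$LE,
                                  n_points = 10)
  femur <- calibrate_long_segment(sil$contour, landmarks$LE, landmarks$GT,
                                  n_points = 6)
  mm_per_px <- compute_scale(landmarks$foot_length_mm, lab$foot_fg)
  # static pelvis tilt (reference value subtracted from dynamic tilt)
  upper <- marker_upper_contour(lab$pelvis)
  pp <- most_posterior_point(upper)
  pl_static <- c(mean(range(upper[, 1])), max(upper[, 2]))
  tilt0 <- tryCatch(pelvis_axis_from_contour(upper, pl_static)$tilt_deg,
                    error = function(e) 0)
  structure(list(foot = foot, tibia = tibia, femur = femur,
                 mm_per_px = mm_per_px, landmarks = landmarks,
                 static_tilt_deg = tilt0, static_PL = pl_static,
                 static_PP = pp,
                 static_silhouette = sil, static_markers = lab),
            class = "body_model")
}
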