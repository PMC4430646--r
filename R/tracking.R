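# Per-frame bottom-up pose estimation: foot by contour-subtraction template
# matching, tibia and femur by ROI-constrained circle-intersection detection
# plus SVD rigid registration, pelvis by the interpolated lateral point.
# The chain is solved foot -> tibia -> femur; the pelvis is independent.

#' Search-grid specification for the foot matcher
#'
#' @param stance_span,swing_span rotation half-spans (deg) around the
#'   predicted foot rotation, by gait phase.
#' @param rot_step rotation grid step, deg.
#' @param trans_span translation half-span around the predicted LM, px.
#' @param trans_step translation grid step, px.
#' @param rot_penalty weak motion prior: pixels of cost added per degree
#'   of deviation from the predicted rotation. Breaks near-flat cost
#'   minima towards temporal continuity; 0 disables it.
#' @return object of class `search_spec`.
#' @export
search_spec <- function(stance_span = 10, swing_span = 30, rot_step = 0.5,
                        trans_span = 5, trans_step = 1, rot_penalty = 0.3) {
  stopifnot(stance_span > 0, swing_span > 0, rot_step > 0,
            trans_span > 0, trans_step > 0, rot_penalty >= 0)
  structure(list(stance_span = stance_span, swing_span = swing_span,
                 rot_step = rot_step, trans_span = trans_span,
                 trans_step = trans_step, rot_penalty = rot_penalty),
            class = "search_spec")
}

#' Constant-velocity point prediction
#'
#' Linear extrapolation from the previous two positions; with a single
#' previous position the prediction is that position (cold start).
#'
#' @param p_prev position at the previous frame.
#' @param p_prev2 position two frames back, or `NULL`.
#' @return predicted position `c(x, y)`.
#' @export
predict_point <- function(p_prev, p_prev2 = NULL) {
  if (is.null(p_prev2)) return(p_prev)
  p_prev + (p_prev - p_prev2)
}

#' Track the foot by contour-subtraction template matching
#'
#' Exhaustive grid search over rotations (about the predicted LM, within
#' the phase-dependent span) and translations. The cost of a candidate
#' pose is the number of active pixels in the symmetric difference between
#' the rasterized template contour and the posterior half of the observed
#' foot-marker contour; ties are broken by smallest displacement from the
#' prediction, then smallest rotation offset.
#'
#' @param foot_marker observed foot blob.
#' @param model a [calibrate_foot()] result.
#' @param lm_pred predicted LM position, px.
#' @param phase `"stance"` or `"swing"`.
#' @param search a [search_spec()].
#' @param rot_center centre of the rotation span, deg (the predicted foot
#'   rotation; 0 at cold start).
#' @param trans_span optional override of the translation half-span.
#' @param use_posterior_half match against the posterior half of the
#'   observed contour (default); disabled when the two socks are merged
#'   into one blob, where the posterior-half cut is meaningless.
#' @return list with `tf` (CS_T -> CS_I [tf2d()]), `cost`, `rotation_deg`,
#'   `displacement`.
#' @export
track_foot <- function(foot_marker, model, lm_pred, phase = "stance",
                       search = search_spec(), rot_center = 0,
                       trans_span = NULL, use_posterior_half = TRUE,
                       rot_span = NULL) {
  if (is.null(foot_marker))
    gait2d_stop("gait2d_tracking_gap", "foot marker missing in frame")
  span <- if (is.null(rot_span)) {
    if (phase == "stance") search$stance_span else search$swing_span
  } else rot_span
  if (is.null(trans_span)) trans_span <- search$trans_span
  obs <- foot_marker$contour
  one_sided <- !use_posterior_half
  # the posterior half of the observed contour is cut per candidate
  # rotation along the (rotated) foot axis, so that it selects the same
  # material region of the foot as the calibrated template
  cut_T <- if (is.null(model$cut_T)) mean(range(obs[, 1])) - lm_pred[1]
           else model$cut_T

  thetas <- seq(rot_center - span, rot_center + span, by = search$rot_step)
  dgrid <- expand.grid(dx = seq(-trans_span, trans_span, by = search$trans_step),
                       dy = seq(-trans_span, trans_span, by = search$trans_step))
  # local raster holding the observed posterior contour
  pad <- trans_span + 5
  tpl_r <- max(sqrt(rowSums(model$template^2)))
  x0 <- floor(min(obs[, 1], lm_pred[1] - tpl_r) - pad)
  y0 <- floor(min(obs[, 2], lm_pred[2] - tpl_r) - pad)
  Wl <- ceiling(max(obs[, 1], lm_pred[1] + tpl_r) + pad) - x0 + 1
  Hl <- ceiling(max(obs[, 2], lm_pred[2] + tpl_r) + pad) - y0 + 1
  O <- rep(FALSE, Wl * Hl)
  oidx_all <- (obs[, 1] - x0) + (obs[, 2] - y0) * Wl + 1
  obs_rel <- sweep(obs, 2, lm_pred)

  best <- NULL
  doff <- dgrid$dx + dgrid$dy * Wl
  ddist <- sqrt(dgrid$dx^2 + dgrid$dy^2)
  for (th in thetas) {
    a <- th * pi / 180
    sel <- if (use_posterior_half)
      obs_rel[, 1] * cos(a) + obs_rel[, 2] * sin(a) <= cut_T
    else rep(TRUE, nrow(obs))
    oidx <- unique(oidx_all[sel])
    O[oidx] <- TRUE
    nO <- length(oidx)
    P <- rotate_points(model$template, th)
    Q <- unique(round(sweep(P, 2, lm_pred, `+`)))
    qidx <- (Q[, 1] - x0) + (Q[, 2] - y0) * Wl + 1
    nQ <- nrow(Q)
    idx <- outer(qidx, doff, `+`)
    valid <- idx >= 1 & idx <= Wl * Hl
    idx[!valid] <- 1L
    mm <- matrix(O[idx] & valid, nrow = nQ)
    m <- colSums(mm)
    O[oidx] <- FALSE
    # merged-sock frames: the observed contour contains both feet, so
    # only unmatched template pixels count (one-sided subtraction)
    cost <- if (one_sided) nQ - m else nQ + nO - 2 * m
    cost <- cost + search$rot_penalty * abs(th - rot_center)
    j <- order(cost, ddist, abs(rep(th - rot_center, length(cost))))[1]
    cand <- list(cost = cost[j], theta = th, dx = dgrid$dx[j], dy = dgrid$dy[j],
                 disp = ddist[j])
    if (is.null(best) || cand$cost < best$cost ||
        (cand$cost == best$cost && (cand$disp < best$disp ||
         (cand$disp == best$disp &&
          abs(cand$theta - rot_center) < abs(best$theta - rot_center)))))
      best <- cand
  }
  lm_fit <- lm_pred + c(best$dx, best$dy)
  list(tf = tf2d(best$theta, lm_fit[1], lm_fit[2]),
       cost = best$cost, rotation_deg = best$theta,
       displacement = best$disp)
}

#' Detect segment reference points as ROI-constrained circle intersections
#'
#' Each template reference point is mapped to the image through the
#' first-approximation transform; within a square region of interest
#' around it, the silhouette-contour point whose distance to the segment
#' centre best matches the calibrated circle radius is taken as the
#' correspondence (omitted when the ROI holds no acceptable point, e.g.
#' under contralateral-leg occlusion).
#'
#' @param contour silhouette contour (n x 2 px).
#' @param model a [calibrate_long_segment()] result.
#' @param first_tf first-approximation [tf2d()] (CS_T -> CS_I).
#' @param center_I segment centre landmark position in the frame, px.
#' @param roi_half ROI half-size, px (10 x 10 px window).
#' @param tol max | |y - center| - r | for an intersection, px.
#' @return list with `p` (template points used, CS_T), `y` (detected
#'   image points), `idx` (template row indices).
#' @export
detect_segment_points <- function(contour, model, first_tf, center_I,
                                  roi_half = 5, tol = 2.5) {
  pred <- tf2d_apply(first_tf, model$template)
  dist_c <- sqrt((contour[, 1] - center_I[1])^2 +
                 (contour[, 2] - center_I[2])^2)
  keep_p <- matrix(NA_real_, 0, 2); keep_y <- matrix(NA_real_, 0, 2)
  idx <- integer(0)
  for (k in seq_len(nrow(pred))) {
    sel <- which(abs(contour[, 1] - pred[k, 1]) <= roi_half &
                 abs(contour[, 2] - pred[k, 2]) <= roi_half)
    if (!length(sel)) next
    err <- abs(dist_c[sel] - model$radii[k])
    j <- which.min(err)
    if (err[j] > tol) next
    keep_p <- rbind(keep_p, model$template[k, ])
    keep_y <- rbind(keep_y, contour[sel[j], ])
    idx <- c(idx, k)
  }
  list(p = keep_p, y = keep_y, idx = idx)
}

#' Least-squares rigid registration of paired points (SVD)
#'
#' Finds the proper rigid transform (rotation + translation, determinant
#' forced to +1) minimizing the sum of squared distances between
#' transformed template points and their image correspondences, via the
#' centroid-demeaned cross-covariance SVD.
#'
#' @param p n x 2 template points.
#' @param y n x 2 corresponding target points.
#' @return a [tf2d()] with `y ~ R p + t`.
#' @export
rigid_fit_svd <- function(p, y) {
  if (is.null(nrow(p)) || nrow(p) < 2 || nrow(p) != nrow(y))
    gait2d_stop("gait2d_insufficient_points",
                "rigid fit needs at least 2 point pairs")
  pc <- colMeans(p); yc <- colMeans(y)
  P <- sweep(p, 2, pc); Y <- sweep(y, 2, yc)
  if (max(abs(P)) < 1e-12)
    gait2d_stop("gait2d_insufficient_points",
                "rigid fit is degenerate: coincident template points")
  H <- t(P) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t_vec <- yc - as.vector(R %*% pc)
  tf2d(atan2(R[2, 1], R[1, 1]) * 180 / pi, t_vec[1], t_vec[2])
}

# transform placing a segment at rotation `rot` with its centre landmark
# at center_I (the "registration of first approximation")
segment_first_approx <- function(model, center_I, rot) {
  a <- rot * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t_vec <- center_I - as.vector(R %*% model$center_T)
  tf2d(rot, t_vec[1], t_vec[2])
}

# Knee position from the rigid segment lengths: intersection of circles
# of radius L_tib around the ankle (LM) and L_fem around the hip (GT),
# taking the anterior solution (the knee never hyperextends in gait).
# Returns NULL when the geometry is degenerate.
knee_from_triangle <- function(lm, gt, L_t, L_f) {
  v <- gt - lm
  d <- sqrt(sum(v^2))
  if (d < 1e-9 || d <= abs(L_f - L_t)) return(NULL)
  if (d >= L_t + L_f) return(lm + v / d * L_t)   # straight leg
  a <- (L_t^2 - L_f^2 + d^2) / (2 * d)
  h <- sqrt(max(L_t^2 - a^2, 0))
  base <- lm + a * v / d
  perp <- c(-v[2], v[1]) / d
  c1 <- base + h * perp; c2 <- base - h * perp
  w <- lm - gt
  cr <- function(p) w[1] * (p[2] - gt[2]) - w[2] * (p[1] - gt[1])
  if (cr(c1) > 0) c1 else c2
}

# rms residual of a fit evaluated on pairs
fit_residual <- function(tf, p, y) {
  e <- tf2d_apply(tf, p) - y
  sqrt(mean(rowSums(e^2)))
}

#' Track a long segment (tibia or femur)
#'
#' A first-approximation registration rotates the calibrated
#' centre-to-distal axis onto the centre-to-predicted-distal direction and
#' places the centre landmark; reference points are then detected with
#' [detect_segment_points()] and registered with [rigid_fit_svd()] (one
#' refinement pass). With fewer than 2 correspondences the first
#' approximation is returned flagged as degraded.
#'
#' @param contour silhouette contour.
#' @param model a [calibrate_long_segment()] result.
#' @param center_I centre landmark position in the frame (LM for the
#'   tibia, LE for the femur), px.
#' @param distal_pred predicted distal landmark position, px.
#' @param cold_start when TRUE, sweep a coarse rotation grid around the
#'   first approximation and keep the orientation with the most
#'   correspondences (used on the first cycle frame, where no velocity
#'   history exists).
#' @return list with `tf` (CS_T -> CS_I), `degraded`, `n_pairs`,
#'   `residual`.
#' @export
track_long_segment <- function(contour, model, center_I, distal_pred,
                               cold_start = FALSE) {
  if (is.null(center_I))
    gait2d_stop("gait2d_chain_broken",
                "centre landmark unavailable: bottom-up chain broken")
  base_rot <- vec_angle_deg(distal_pred - center_I) -
    vec_angle_deg(model$distal_I - model$center_I)
  make_tf <- function(rot) segment_first_approx(model, center_I, rot)
  rots <- if (cold_start) base_rot + seq(-40, 40, by = 2) else base_rot
  best <- NULL
  for (rot in rots) {
    tf0 <- make_tf(rot)
    cor <- detect_segment_points(contour, model, tf0, center_I)
    n <- nrow(cor$p)
    res <- if (n >= 2) {
      fit <- rigid_fit_svd(cor$p, cor$y)
      fit_residual(fit, cor$p, cor$y)
    } else Inf
    if (is.null(best) || n > best$n || (n == best$n && res < best$res))
      best <- list(tf0 = tf0, n = n, res = res)
  }
  cor <- detect_segment_points(contour, model, best$tf0, center_I)
  if (nrow(cor$p) < 2)
    return(list(tf = best$tf0, degraded = TRUE, n_pairs = nrow(cor$p),
                residual = NA_real_))
  fit <- rigid_fit_svd(cor$p, cor$y)
  # one refinement pass with the fitted transform
  cor2 <- detect_segment_points(contour, model, fit, center_I)
  if (nrow(cor2$p) >= 2) {
    fit <- rigid_fit_svd(cor2$p, cor2$y)
    cor <- cor2
  }
  list(tf = fit, degraded = FALSE, n_pairs = nrow(cor$p),
       residual = fit_residual(fit, cor$p, cor$y))
}

#' Track the pelvis at one frame
#'
#' The posterior point PP of the pelvis-marker upper contour is detected
#' automatically; the lateral point is placed at
#' `PL_i = PP_i + (d_x(i), 0)` using the double calibration, and the
#' pelvis axis orientation is fitted around PL.
#'
#' @param pelvis_blob labelled pelvis marker.
#' @param calib a [double_calibrate_pelvis()] result.
#' @param i_rel frame index within the cycle (0 = first cycle frame).
#' @param axis_halfwidth window halfwidth for the axis fit, px.
#' @return list with `PL`, `PP`, `tilt_deg`, `partial`.
#' @export
track_pelvis <- function(pelvis_blob, calib, i_rel, axis_halfwidth = 20) {
  if (is.null(pelvis_blob))
    gait2d_stop("gait2d_tracking_gap", "pelvis marker missing in frame")
  upper <- marker_upper_contour(pelvis_blob)
  PP <- most_posterior_point(upper)
  PL <- c(PP[1] + pelvis_dx(calib, i_rel), PP[2])
  ax <- pelvis_axis_from_contour(upper, PL, axis_halfwidth)
  list(PL = unname(PL), PP = unname(PP), tilt_deg = ax$tilt_deg,
       partial = ax$partial)
}

#' Joint angles from a frame pose
#'
#' Each joint angle is the signed difference between the anatomical-axis
#' orientations of the adjoining segments in CS_I, with the static-pose
#' offsets subtracted so that the calibration posture reads zero for all
#' joints (the 90 deg foot/shank offset is absorbed by the convention).
#' Flexion / dorsiflexion positive.
#'
#' @param pose list with `tf_foot`, `tf_tibia`, `tf_femur` ([tf2d()]
#'   CS_T -> CS_I, possibly NULL) and `tilt_deg`.
#' @param model a [calibrate_body()] result.
#' @return named numeric vector: `hip`, `knee`, `ankle`, `pelvic_tilt`
#'   (deg; NA where the upstream transform is missing).
#' @export
compute_joint_angles <- function(pose, model) {
  alpha <- function(tf, seg) {
    if (is.null(tf)) return(NA_real_)
    anat <- tf2d_compose(tf, tf2d_inverse(seg$T_A_from_T))
    anat$theta_deg - (-seg$T_A_from_T$theta_deg)   # static anatomical angle
  }
  a_foot <- alpha(pose$tf_foot, model$foot)
  a_tib <- alpha(pose$tf_tibia, model$tibia)
  a_fem <- alpha(pose$tf_femur, model$femur)
  tilt <- if (is.null(pose$tilt_deg)) NA_real_ else
    pose$tilt_deg - model$static_tilt_deg
  c(hip = a_fem - tilt, knee = a_fem - a_tib, ankle = a_foot - a_tib,
    pelvic_tilt = tilt)
}

#' Track one gait cycle bottom-up
#'
#' Runs the full per-frame chain (foot template matching, tibia and femur
#' circle-intersection SVD registration, pelvis double-calibration
#' tracking) over the frames of one gait cycle and derives joint angles.
#' Missing-marker frames and degraded fits are linearly interpolated in
#' transform parameters and flagged.
#'
#' @param features per-frame list, each with `sil_contour` (silhouette
#'   contour) and `markers` (a [label_markers()] result), for frames
#'   `cycle[1] .. cycle[2]`.
#' @param model a [calibrate_body()] result.
#' @param pelvis_calib a [double_calibrate_pelvis()] for this cycle.
#' @param stance_frames integer frames (absolute indices) classified as
#'   stance for the foreground foot.
#' @param cycle `c(first_frame, last_frame)` absolute indices.
#' @param search a [search_spec()].
#' @return data.frame with one row per frame: transforms (angle deg,
#'   translation px) per segment, landmark positions, joint angles, match
#'   cost and flags.
#' @export
track_cycle <- function(features, model, pelvis_calib, stance_frames,
                        cycle, search = search_spec()) {
  frames <- cycle[1]:cycle[2]
  n <- length(frames)
  # frame-stamped two-deep histories; merged-sock frames never update the
  # foot histories, so predictions coast through a crossing at the last
  # clean velocity
  hist_new <- function() list(f = numeric(0), v = NULL)
  hist_push <- function(h, fr, val) {
    h$f <- c(h$f, fr); h$v <- rbind(h$v, val)
    k <- length(h$f)
    if (k > 2) { h$f <- h$f[(k - 1):k]; h$v <- h$v[(k - 1):k, , drop = FALSE] }
    h
  }
  hist_pred <- function(h, fr) {
    k <- length(h$f)
    if (k == 0) return(NULL)
    if (k == 1) return(unname(h$v[1, ]))
    unname(h$v[k, ] + (h$v[k, ] - h$v[k - 1, ]) /
             (h$f[k] - h$f[k - 1]) * (fr - h$f[k]))
  }
  h_lm <- hist_new(); h_rot <- hist_new()
  h_le <- hist_new(); h_gt <- hist_new()
  h_tib <- hist_new(); h_fem <- hist_new()
  prev_merged <- FALSE
  out <- vector("list", n)
  lm0 <- model$foot$LM
  foot_c0 <- colMeans(model$static_markers$foot_fg$contour)

  na_row <- function(fr, flag = "gap") {
    data.frame(frame = fr, foot_theta = NA_real_, foot_tx = NA_real_,
               foot_ty = NA_real_, tibia_theta = NA_real_, tibia_tx = NA_real_,
               tibia_ty = NA_real_, femur_theta = NA_real_, femur_tx = NA_real_,
               femur_ty = NA_real_, lm_x = NA_real_, lm_y = NA_real_,
               le_x = NA_real_, le_y = NA_real_, gt_x = NA_real_,
               gt_y = NA_real_, pl_x = NA_real_, pl_y = NA_real_,
               pp_x = NA_real_, pp_y = NA_real_, hip = NA_real_,
               knee = NA_real_, ankle = NA_real_, pelvic_tilt = NA_real_,
               match_cost = NA_real_, tibia_pairs = NA_integer_,
               femur_pairs = NA_integer_, flags = flag,
               stringsAsFactors = FALSE)
  }

  for (j in seq_len(n)) {
    fr <- frames[j]
    ft <- features[[j]]
    mk <- ft$markers
    if (is.null(mk) || is.null(mk$foot_fg) || is.null(mk$pelvis)) {
      out[[j]] <- na_row(fr)
      next
    }
    if (isTRUE(mk$merged)) {
      # while the socks overlap, the foreground foot is unobservable;
      # the frame is bridged by interpolation between clean anchors
      out[[j]] <- na_row(fr, "merged_feet")
      prev_merged <- TRUE
      next
    }
    out[[j]] <- tryCatch({
    flags <- character(0)
    if (!is.null(mk$warnings) && length(mk$warnings))
      flags <- c(flags, mk$warnings)
    if (isTRUE(mk$merged)) flags <- c(flags, "merged_feet")

    phase <- if (fr %in% stance_frames) "stance" else "swing"

    # --- foot ---
    cold <- length(h_lm$f) == 0
    reacquire <- prev_merged
    rot_center <- if (length(h_rot$f) == 0) 0 else hist_pred(h_rot, fr)
    rot_center <- min(max(rot_center, -75), 45)   # plausible foot pitch
    # velocity extrapolation is trusted only with two fresh, consecutive
    # clean observations; otherwise (cold start, after a sock merge, or
    # stale history) the LM is re-anchored on the labelled blob centroid
    # through the calibrated centroid-to-LM offset at the predicted pitch
    fresh_hist <- length(h_lm$f) == 2 && (h_lm$f[2] - h_lm$f[1]) == 1 &&
      (fr - h_lm$f[2]) == 1
    anchored_lm <- !(fresh_hist && !reacquire && !cold)
    lm_pred <- if (anchored_lm) {
      mk$foot_fg$centroid +
        as.vector(rotate_points(matrix(lm0 - foot_c0, 1, 2), rot_center))
    } else hist_pred(h_lm, fr)
    foot_fit <- track_foot(mk$foot_fg, model$foot, lm_pred,
                           phase = if (cold) "swing" else phase,
                           search = search, rot_center = rot_center,
                           trans_span = if (anchored_lm) 9 else NULL,
                           rot_span = if (reacquire) 75 else NULL)
    tf_foot <- foot_fit$tf
    LM_i <- c(tf_foot$tx, tf_foot$ty)

    # --- pelvis (independent of the leg chain) ---
    pel <- track_pelvis(mk$pelvis, pelvis_calib, fr - cycle[1])
    if (pel$partial) flags <- c(flags, "pelvis_window_partial")
    # pelvis-fixed prediction of GT (statically calibrated PL -> GT
    # offset rotated by the measured tilt change)
    gt_anchor <- if (!is.null(model$static_PL)) {
      pel$PL + as.vector(rotate_points(
        matrix(model$landmarks$GT - model$static_PL, 1, 2),
        pel$tilt_deg - model$static_tilt_deg))
    } else NULL
    L_tib <- sqrt(sum((model$tibia$distal_I - model$tibia$center_I)^2))
    L_fem <- sqrt(sum((model$femur$distal_I - model$femur$center_I)^2))
    le_geom <- if (!is.null(gt_anchor))
      knee_from_triangle(LM_i, gt_anchor, L_tib, L_fem) else NULL

    # a long-segment track with few correspondences is re-acquired by a
    # coarse orientation sweep about a fresh prediction
    with_recovery <- function(fit, seg_model, center, distal_pred) {
      if (!fit$degraded && fit$n_pairs >= 3) return(fit)
      retry <- track_long_segment(ft$sil_contour, seg_model, center,
                                  distal_pred, cold_start = TRUE)
      better <- retry$n_pairs > fit$n_pairs ||
        (retry$n_pairs == fit$n_pairs && !retry$degraded &&
         (is.na(fit$residual) || (!is.na(retry$residual) &&
                                  retry$residual < fit$residual)))
      if (better) retry else fit
    }

    # a low-support fit whose orientation jumps implausibly between
    # frames is rejected in favour of the extrapolated orientation
    gate_jump <- function(fit, th_hist, seg_model, center, fr, max_jump = 12) {
      if (!length(th_hist$f) || fit$n_pairs > 3) return(fit)
      pred_th <- hist_pred(th_hist, fr)
      if (abs(fit$tf$theta_deg - pred_th) <= max_jump) return(fit)
      list(tf = segment_first_approx(seg_model, center, pred_th),
           degraded = TRUE, n_pairs = fit$n_pairs, residual = NA_real_)
    }

    # --- tibia ---
    # the knee prediction combines the rigid-length geometry (circles of
    # the calibrated tibia/femur lengths around LM and the pelvis-fixed
    # GT) with velocity extrapolation as fallback
    le_pred <- if (!is.null(le_geom)) le_geom
    else if (length(h_le$f) == 0)
      LM_i + (model$tibia$distal_I - model$tibia$center_I)
    else hist_pred(h_le, fr)
    tib <- track_long_segment(ft$sil_contour, model$tibia, LM_i, le_pred,
                              cold_start = length(h_le$f) == 0 || reacquire)
    tib <- with_recovery(tib, model$tibia, LM_i, le_pred)
    # gate low-support tibia fits against the geometric knee direction
    if (!is.null(le_geom)) {
      tib_anchor_rot <- vec_angle_deg(le_geom - LM_i) -
        vec_angle_deg(model$tibia$distal_I - model$tibia$center_I)
      if (tib$n_pairs <= 5 && abs(tib$tf$theta_deg - tib_anchor_rot) > 15)
        tib <- list(tf = segment_first_approx(model$tibia, LM_i, tib_anchor_rot),
                    degraded = TRUE, n_pairs = tib$n_pairs, residual = NA_real_)
    } else {
      tib <- gate_jump(tib, h_tib, model$tibia, LM_i, fr)
    }
    if (tib$degraded) flags <- c(flags, "tibia_degraded")
    LE_i <- tf2d_apply(tib$tf, model$tibia$distal_T)

    # --- femur ---
    gt_pred <- if (!is.null(gt_anchor)) gt_anchor
    else if (length(h_gt$f) == 0)
      LE_i + (model$femur$distal_I - model$femur$center_I)
    else hist_pred(h_gt, fr)
    fem <- track_long_segment(ft$sil_contour, model$femur, LE_i, gt_pred,
                              cold_start = length(h_gt$f) == 0 || reacquire)
    fem <- with_recovery(fem, model$femur, LE_i, gt_pred)
    # anatomical consistency: a femur whose orientation contradicts the
    # pelvis-anchored hip position has locked onto the contralateral
    # thigh; replace it by the anchored registration
    if (!is.null(gt_anchor)) {
      anchor_rot <- vec_angle_deg(gt_anchor - LE_i) -
        vec_angle_deg(model$femur$distal_I - model$femur$center_I)
      if (abs(fem$tf$theta_deg - anchor_rot) > 10) {
        fem <- list(tf = segment_first_approx(model$femur, LE_i, anchor_rot),
                    degraded = FALSE, n_pairs = fem$n_pairs,
                    residual = NA_real_)
        flags <- c(flags, "femur_anchored")
      }
    }
    if (fem$degraded) flags <- c(flags, "femur_degraded")
    GT_i <- tf2d_apply(fem$tf, model$femur$distal_T)

    pose <- list(tf_foot = tf_foot, tf_tibia = tib$tf, tf_femur = fem$tf,
                 tilt_deg = pel$tilt_deg)
    ang <- compute_joint_angles(pose, model)

    if (!isTRUE(mk$merged)) {
      h_lm <- hist_push(h_lm, fr, LM_i)
      h_rot <- hist_push(h_rot, fr, foot_fit$rotation_deg)
    }
    if (!tib$degraded) {
      h_le <- hist_push(h_le, fr, LE_i)
      h_tib <- hist_push(h_tib, fr, tib$tf$theta_deg)
    }
    if (!fem$degraded) {
      h_gt <- hist_push(h_gt, fr, GT_i)
      h_fem <- hist_push(h_fem, fr, fem$tf$theta_deg)
    }
    prev_merged <- isTRUE(mk$merged)

    data.frame(
      frame = fr,
      foot_theta = tf_foot$theta_deg, foot_tx = tf_foot$tx, foot_ty = tf_foot$ty,
      tibia_theta = tib$tf$theta_deg, tibia_tx = tib$tf$tx, tibia_ty = tib$tf$ty,
      femur_theta = fem$tf$theta_deg, femur_tx = fem$tf$tx, femur_ty = fem$tf$ty,
      lm_x = LM_i[1], lm_y = LM_i[2], le_x = LE_i[1], le_y = LE_i[2],
      gt_x = GT_i[1], gt_y = GT_i[2],
      pl_x = pel$PL[1], pl_y = pel$PL[2], pp_x = pel$PP[1], pp_y = pel$PP[2],
      hip = ang[["hip"]], knee = ang[["knee"]], ankle = ang[["ankle"]],
      pelvic_tilt = ang[["pelvic_tilt"]],
      match_cost = foot_fit$cost,
      tibia_pairs = tib$n_pairs, femur_pairs = fem$n_pairs,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
    }, gait2d_error = function(e) na_row(fr))
  }
  res <- do.call(rbind, out)
  interpolate_gaps(res)
}

# Linearly interpolate transform parameters, landmarks, angles and the
# pelvic tilt across gap frames; interpolated frames keep the "gap" flag.
interpolate_gaps <- function(res) {
  gap <- is.na(res$foot_theta) | is.na(res$hip)
  if (!any(gap) || all(gap)) return(res)
  num_cols <- setdiff(names(res)[vapply(res, is.numeric, logical(1))], "frame")
  ok <- which(!gap)
  for (cl in num_cols) {
    res[[cl]][gap] <- approx(res$frame[ok], res[[cl]][ok],
                             xout = res$frame[gap], rule = 2)$y
  }
  res$flags[gap] <- paste0(res$flags[gap], ";interpolated")
  res
}
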