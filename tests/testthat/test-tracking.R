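test_that("constant-velocity prediction extrapolates linearly", {
  expect_equal(predict_point(c(10, 0), c(8, 0)), c(12, 0))
  expect_equal(predict_point(c(5, 5), c(5, 5)), c(5, 5))
  expect_equal(predict_point(c(3, 1)), c(3, 1))   # cold start
})

test_that("SVD rigid fit recovers exact transforms to 1e-9", {
  set.seed(31)
  p <- cbind(runif(10, -40, 40), runif(10, -40, 40))
  expect_equal(rigid_fit_svd(p, p)$theta_deg, 0, tolerance = 1e-9)
  tf_true <- tf2d(10, 5, -3)
  y <- tf2d_apply(tf_true, p)
  fit <- rigid_fit_svd(p, y)
  expect_equal(fit$theta_deg, 10, tolerance = 1e-9)
  expect_equal(c(fit$tx, fit$ty), c(5, -3), tolerance = 1e-9)
  # mirrored targets still produce a proper rotation (det +1)
  y_mirror <- cbind(-y[, 1], y[, 2])
  fitm <- rigid_fit_svd(p, y_mirror)
  expect_equal(det(tf2d_rotation(fitm)), 1, tolerance = 1e-12)
  expect_error(rigid_fit_svd(p[1, , drop = FALSE], y[1, , drop = FALSE]),
               class = "gait2d_insufficient_points")
  same <- matrix(1, 5, 2)
  expect_error(rigid_fit_svd(same, y[1:5, ]),
               class = "gait2d_insufficient_points")
})

test_that("full-set fit residual is optimal over subset fits", {
  set.seed(32)
  p <- cbind(runif(8, -40, 40), runif(8, -40, 40))
  y <- tf2d_apply(tf2d(6, 2, -1), p) + matrix(rnorm(16, sd = 0.5), 8, 2)
  full <- rigid_fit_svd(p, y)
  res_full <- sum((tf2d_apply(full, p) - y)^2)
  for (k in 1:10) {
    sub <- sample(8, 4)
    fit_sub <- rigid_fit_svd(p[sub, ], y[sub, ])
    expect_lte(res_full, sum((tf2d_apply(fit_sub, p) - y)^2) + 1e-9)
  }
})

test_that("foot matching is exact on the static frame and recovers rotations", {
  blob <- render_foot_blob(theta_deg = 0, ankle_px = c(150, 150))
  fm <- calibrate_foot(blob, LM = c(150, 150))
  fit0 <- track_foot(blob, fm, lm_pred = c(150, 150), phase = "stance")
  expect_equal(fit0$cost, 0)                       # identity, zero cost
  expect_equal(fit0$rotation_deg, 0)
  expect_equal(c(fit0$tf$tx, fit0$tf$ty), c(150, 150))
  # a 5 deg rotated rendering is recovered within the rotation step
  rot5 <- render_foot_blob(theta_deg = 5, ankle_px = c(150, 150))
  fit5 <- track_foot(rot5, fm, lm_pred = c(150, 150), phase = "swing")
  expect_equal(fit5$rotation_deg, 5, tolerance = 0.5)
  # a 20 deg rotation under the stance span clamps at the 10 deg boundary
  rot20 <- render_foot_blob(theta_deg = 20, ankle_px = c(150, 150))
  fit20 <- track_foot(rot20, fm, lm_pred = c(150, 150), phase = "stance",
                      rot_center = 0)
  expect_equal(fit20$rotation_deg, 10)
})

test_that("segment reference points are redetected in their ROIs", {
  W <- 200; H <- 500; w <- 17
  center <- c(100, 100); distal <- c(100, 420)
  px <- gait2d:::rasterize_capsule(center, distal, w, W, H)
  mask <- matrix(0L, W, H); mask[px] <- 1L
  ct <- extract_contour(mask)
  tib <- calibrate_long_segment(ct, center, distal, 10)
  ident <- tf2d(0, tib$origin_T_I[1], tib$origin_T_I[2])
  cor0 <- detect_segment_points(ct, tib, ident, center)
  expect_equal(nrow(cor0$p), 10)                  # all pairs at calibration
  expect_lte(max(abs(cor0$y - tf2d_apply(ident, cor0$p))), 1)
  # rotate the leg 3 deg about the centre: with the first approximation
  # aligned to the new axis, all pairs are found inside their ROIs
  ct3 <- gait2d:::rotate_points(ct, 3, centre = center)
  tf3 <- gait2d:::segment_first_approx(tib, center, 3)
  cor3 <- detect_segment_points(round(ct3), tib, tf3, center)
  expect_equal(nrow(cor3$p), 10)
  pred3 <- tf2d_apply(tf3, cor3$p)
  expect_lte(max(abs(cor3$y - pred3)), 5)      # within each 10x10 ROI
  # occlude one side: only near-side pairs remain
  ct_half <- ct[ct[, 1] >= 100, , drop = FALSE]
  cor_h <- detect_segment_points(ct_half, tib, ident, center)
  expect_equal(nrow(cor_h$p), 5)
  expect_true(all(cor_h$y[, 1] >= 100))
})

test_that("long-segment tracking recovers a known rotation", {
  W <- 400; H <- 500; w <- 17
  center <- c(200, 100); distal <- c(200, 420)
  px <- gait2d:::rasterize_capsule(center, distal, w, W, H)
  mask <- matrix(0L, W, H); mask[px] <- 1L
  tib <- calibrate_long_segment(extract_contour(mask), center, distal, 10)
  # identity case
  fit0 <- track_long_segment(extract_contour(mask), tib, center, distal)
  expect_lt(abs(fit0$tf$theta_deg), 0.5)
  expect_false(fit0$degraded)
  # render the shank rotated 12 deg about the centre landmark
  rot <- 12
  d2 <- gait2d:::rotate_points(matrix(distal, 1, 2), rot, centre = center)[1, ]
  px2 <- gait2d:::rasterize_capsule(center, d2, w, W, H)
  m2 <- matrix(0L, W, H); m2[px2] <- 1L
  fit <- track_long_segment(extract_contour(m2), tib, center, d2)
  expect_equal(fit$tf$theta_deg, 12, tolerance = 1)
  # empty ROIs: first approximation returned, flagged degraded
  far <- extract_contour(m2) + 200
  fit_d <- track_long_segment(far, tib, center, d2)
  expect_true(fit_d$degraded)
  expect_equal(fit_d$tf$theta_deg,
               gait2d:::vec_angle_deg(d2 - center) -
                 gait2d:::vec_angle_deg(distal - center), tolerance = 1e-9)
})

test_that("pelvis tracking applies the interpolated horizontal offset", {
  px <- expand.grid(x = 80:160, y = 480:500)
  blob <- list(pixels = as.matrix(px), centroid = c(120, 490),
               area = nrow(px), contour = NULL)
  pc <- double_calibrate_pelvis(c(115, 500), c(80, 500),
                                c(125, 500), c(80, 500), M = 10)
  tp <- track_pelvis(blob, pc, i_rel = 5)
  expect_equal(tp$PP, c(80, 500))
  expect_equal(tp$PL[1], 80 + pelvis_dx(pc, 5))    # d_x,5 = 35 + 5*1 = 40
  expect_equal(tp$PL[1], 120)
  expect_equal(tp$tilt_deg, 0, tolerance = 1e-9)
  # at i = 0 the manual anchor is reproduced when PP matches
  tp0 <- track_pelvis(blob, pc, i_rel = 0)
  expect_equal(tp0$PL[1], 115)
})

test_that("joint angles are zero at the static pose and add rotations", {
  tr <- get_trial("comfortable")
  model <- tr$res$model
  static_pose <- list(
    tf_foot = tf2d(0, model$foot$LM[1], model$foot$LM[2]),
    tf_tibia = tf2d(0, model$tibia$origin_T_I[1], model$tibia$origin_T_I[2]),
    tf_femur = tf2d(0, model$femur$origin_T_I[1], model$femur$origin_T_I[2]),
    tilt_deg = model$static_tilt_deg)
  ang <- compute_joint_angles(static_pose, model)
  expect_equal(unname(ang), c(0, 0, 0, 0), tolerance = 1e-9)
  # rotating the femur +10 deg with everything else fixed adds to the hip
  pose2 <- static_pose
  pose2$tf_femur <- tf2d_compose(tf2d(10, 0, 0), static_pose$tf_femur)
  ang2 <- compute_joint_angles(pose2, model)
  expect_equal(ang2[["hip"]], 10, tolerance = 1e-9)
  expect_equal(ang2[["knee"]], 10, tolerance = 1e-9)
  expect_equal(ang2[["ankle"]], 0, tolerance = 1e-9)
  # anatomical transform equals the composition of its two factors
  anat <- tf2d_compose(pose2$tf_femur, tf2d_inverse(model$femur$T_A_from_T))
  manual <- tf2d_matrix(pose2$tf_femur) %*%
    solve(tf2d_matrix(model$femur$T_A_from_T))
  expect_equal(tf2d_matrix(anat), manual, tolerance = 1e-9)
})

test_that("tracked angles match ground truth over a cycle", {
  # trial carries 1 px contour jitter; bounds are on the raw per-frame
  # angle estimates, before filtering and time normalization
  tr <- get_trial("comfortable")
  res <- tr$res; truth <- tr$truth
  cy <- unname(res$cycles[1, ])
  pose <- res$poses[[1]]
  tf <- truth$frames[cy[1]:cy[2], ]
  rms <- function(e) sqrt(mean(e^2, na.rm = TRUE))
  expect_lt(rms(pose$hip - tf$hip_deg), 3.5)
  expect_lt(rms(pose$knee - tf$knee_deg), 4)
  expect_lt(rms(pose$ankle - tf$ankle_deg), 3)
  expect_lt(rms(pose$pelvic_tilt - tf$pelvic_tilt_deg), 1)
  # PL tracked within 2 px horizontally over the cycle
  expect_lt(max(abs(pose$pl_x - tf$pl_x)), 2)
})
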