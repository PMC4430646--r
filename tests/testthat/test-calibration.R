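test_that("foot calibration finds the flat-bottom anatomical axis", {
  blob <- render_foot_blob(theta_deg = 0, ankle_px = c(150, 150))
  fm <- calibrate_foot(blob, LM = c(150, 150))
  expect_lt(abs(fm$axis_angle_deg), 0.5)        # flat bottom -> 0 deg
  # template = posterior half of the marker contour
  xmid <- mean(range(blob$contour[, 1]))
  expect_equal(nrow(fm$template), sum(blob$contour[, 1] <= xmid))
  expect_true(all(fm$template[, 1] + 150 <= xmid))
  # origin at the most posterior contour point
  expect_equal(fm$origin_A[1], min(blob$contour[, 1]))
})

test_that("a rotated foot yields the same axis rotated", {
  blob <- render_foot_blob(theta_deg = 7, ankle_px = c(150, 150))
  fm <- calibrate_foot(blob, LM = c(150, 150))
  expect_equal(fm$axis_angle_deg, 7, tolerance = 0.5)
})

test_that("posterior-half template rule uses the horizontal midpoint", {
  # synthetic square marker spanning x in [100, 200]
  m <- matrix(0L, 260, 120); m[100:200, 40:80] <- 1L
  ct <- extract_contour(m)
  fm <- calibrate_foot(list(contour = ct), LM = c(150, 60))
  expect_true(all(fm$template[, 1] + 150 <= 150))
  expect_equal(sum(ct[, 1] <= 150), nrow(fm$template))
})

test_that("long-segment calibration matches capsule geometry", {
  # vertical capsule: shank of halfwidth w between LM and LE
  W <- 200; H <- 500; w <- 17
  center <- c(100, 100); distal <- c(100, 420)
  px <- gait2d:::rasterize_capsule(center, distal, w, W, H)
  mask <- matrix(0L, W, H); mask[px] <- 1L
  ct <- extract_contour(mask)
  tib <- calibrate_long_segment(ct, center, distal, n_points = 10)
  expect_equal(nrow(tib$template), 10)
  # every reference point sits w +- 1 px off the segment axis
  pts_I <- sweep(tib$template, 2, tib$origin_T_I, `+`)
  expect_true(all(abs(abs(pts_I[, 1] - 100) - w) <= 1))
  # radial band invariant: radii within [0.25, 0.75] of the length
  L <- sqrt(sum((distal - center)^2))
  expect_true(all(tib$radii >= 0.25 * L & tib$radii <= 0.75 * L))
  # CS_T origin is the centroid of the reference points (exact)
  expect_equal(colMeans(tib$template), c(0, 0), tolerance = 1e-12)
  fem <- calibrate_long_segment(ct, center, distal, n_points = 6)
  expect_equal(nrow(fem$template), 6)
})

test_that("landmarks round-trip through the technical frame", {
  W <- 200; H <- 500
  center <- c(100, 100); distal <- c(104, 420)
  px <- gait2d:::rasterize_capsule(center, distal, 17, W, H)
  mask <- matrix(0L, W, H); mask[px] <- 1L
  tib <- calibrate_long_segment(extract_contour(mask), center, distal, 10)
  # CS_I -> CS_T -> CS_I recovers the landmark to 1e-6 px
  T_TI <- tf2d(0, tib$origin_T_I[1], tib$origin_T_I[2])   # CS_T -> CS_I
  expect_equal(tf2d_apply(T_TI, tib$center_T), center, tolerance = 1e-6)
  expect_equal(tf2d_apply(T_TI, tib$distal_T), distal, tolerance = 1e-6)
  # anatomical transform is a proper rigid transform
  R <- tf2d_rotation(tib$T_A_from_T)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("occluded static circles raise a calibration error", {
  W <- 200; H <- 500
  center <- c(100, 100); distal <- c(100, 420)
  px <- gait2d:::rasterize_capsule(center, distal, 17, W, H)
  mask <- matrix(0L, W, H); mask[px] <- 1L
  ct <- extract_contour(mask)
  half <- ct[ct[, 1] >= 100, , drop = FALSE]   # one side missing
  expect_error(calibrate_long_segment(half, center, distal, 10),
               class = "gait2d_calibration_failed")
})

test_that("pelvis double calibration reproduces the interpolation rule", {
  pc <- double_calibrate_pelvis(PL_first = c(130, 500), PP_first = c(100, 500),
                                PL_last = c(141, 502), PP_last = c(101, 502),
                                M = 10)
  expect_equal(pc$d_x_first, 30)
  expect_equal(pc$d_x_last, 40)
  expect_equal(pc$delta, 1)                    # (40 - 30) / 10
  expect_equal(pelvis_dx(pc, 5), 35)
  expect_equal(pelvis_dx(pc, 0), pc$d_x_first) # anchors reproduced exactly
  expect_equal(pelvis_dx(pc, 10), pc$d_x_last)
  pc0 <- double_calibrate_pelvis(c(130, 0), c(100, 0), c(130, 0), c(100, 0), 8)
  expect_equal(pc0$delta, 0)
  expect_equal(pelvis_dx(pc0, 3), 30)
  expect_error(double_calibrate_pelvis(c(1, 1), c(0, 0), c(1, 1), c(0, 0), 0),
               class = "gait2d_bad_calibration")
})

test_that("pelvis axis fit recovers the upper-contour slope", {
  x <- 60:140
  flat <- cbind(x, 500)
  expect_equal(pelvis_axis_from_contour(flat, PL = c(100, 500))$tilt_deg, 0)
  slope <- cbind(x, 500 + 0.1 * (x - 100))
  ax <- pelvis_axis_from_contour(slope, PL = c(100, 500))
  expect_equal(ax$tilt_deg, atan(0.1) * 180 / pi, tolerance = 1e-9)
  expect_false(ax$partial)
  # clipped window: fit still returned, flagged partial
  clipped <- slope[x >= 92, , drop = FALSE]
  ax2 <- pelvis_axis_from_contour(clipped, PL = c(100, 500))
  expect_true(ax2$partial)
  expect_equal(ax2$tilt_deg, atan(0.1) * 180 / pi, tolerance = 1e-9)
  expect_error(pelvis_axis_from_contour(slope[x > 118, , drop = FALSE],
                                        PL = c(100, 500)),
               class = "gait2d_degenerate_contour")
})
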