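test_that("trajectory timing matches the gait-spec arithmetic", {
  spec <- trial_spec("comfortable")          # stride 1.2 s @ 50 fps
  tr <- generate_gait_trajectory(spec)
  hs <- tr$events$hs_fg
  expect_gte(length(hs), 2)
  expect_equal(diff(hs)[1], 60)              # 1.2 s * 50 fps
  expect_equal(tr$params$cadence_steps_min, 100)   # 2 steps / 1.2 s
  expect_equal(tr$params$stride_length_m, 1.25 * 1.2)  # speed x time
})

test_that("non-physical specs are rejected", {
  expect_error(gait_spec(walking_speed = 3, stride_time = 1.2),
               class = "gait2d_nonphysical_spec")
})

test_that("zero-amplitude joint curves give constant segment orientations", {
  flat <- list(a0 = 0, a = 0, b = 0)
  spec <- tiny_spec(joint_curves = list(hip = flat, knee = flat,
                                        ankle = flat, pelvic_tilt = flat))
  tr <- generate_gait_trajectory(spec)
  for (col in c("theta_f_fg", "theta_s_fg", "theta_foot_fg"))
    expect_equal(diff(range(tr$frames[[col]])), 0)
})

test_that("ground-truth angles are consistent with landmark geometry", {
  spec <- trial_spec("comfortable")
  tr <- generate_gait_trajectory(spec)
  f <- tr$frames
  seg_angle <- function(proximal_x, proximal_y, distal_x, distal_y) {
    atan2(distal_x - proximal_x, -(distal_y - proximal_y)) * 180 / pi
  }
  th_f <- seg_angle(f$gt_x, f$gt_y, f$le_x, f$le_y)
  th_s <- seg_angle(f$le_x, f$le_y, f$lm_x, f$lm_y)
  expect_equal(th_f - f$pelvic_tilt_deg, f$hip_deg, tolerance = 0.1)
  expect_equal(th_f - th_s, f$knee_deg, tolerance = 0.1)
})

test_that("declared events sit on extrema of the centroid distance", {
  tr <- generate_gait_trajectory(trial_spec("comfortable"))
  d <- tr$frames$foot_fg_cx - tr$frames$pelvis_cx
  for (hs in tr$events$hs_fg) {
    w <- max(1, hs - 1):min(length(d), hs + 1)
    expect_lte(abs(hs - w[which.max(d[w])]), 1)
    expect_gte(d[hs], max(d) - 5)   # near the global excursion
  }
})

test_that("ground truth in mm is invariant to rendering resolution", {
  a <- generate_gait_trajectory(tiny_spec())
  b <- generate_gait_trajectory(tiny_spec(image_size = c(1280, 720),
                                          mm_per_px = 3))
  expect_equal(a$params, b$params)
  expect_equal(a$frames$hip_deg, b$frames$hip_deg)
  # px landmarks scale by the mm/px ratio
  expect_equal(a$frames$lm_x * 6, b$frames$lm_x * 3, tolerance = 1e-9)
})

test_that("rendered frames expose the expected garment blobs", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  for (i in c(5, 25)) {
    fr <- render_frame(tr, spec, i)
    # oracle: connected components of the renderer's own white-part mask
    white <- matrix(as.integer(fr$parts %in% c(4L, 5L, 8L)), nrow(fr$parts))
    ncc <- max(EBImage::bwlabel(white))
    expect_gte(ncc, 2); expect_lte(ncc, 3)
    # one pelvis blob and 1-2 foot blobs recoverable by colour thresholding
    hv <- gait2d:::frame_hsv(fr$rgb)
    wmask <- matrix(as.integer(hv$s < 0.2 & hv$v > 0.8), nrow(fr$parts))
    lab <- EBImage::bwlabel(wmask)
    ncc2 <- sum(tabulate(lab[lab > 0]) >= 50)
    expect_equal(ncc2, ncc)
    # the true LM lies inside the rendered silhouette
    lm <- round(c(tr$frames$lm_x[i], tr$frames$lm_y[i]))
    expect_gt(fr$parts[lm[1], lm[2]], 0)
  }
})

test_that("empty trajectories render only the static reference", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  out <- render_frames(tr, spec, frames = integer(0))
  expect_length(out$frames, 0)
  expect_true(!is.null(out$static$rgb))
})

test_that("noise is deterministic, and zero noise is the identity", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  fr <- render_frame(tr, spec, 10)$rgb
  expect_identical(perturb_frame(fr, noise_spec(), 10), fr)
  n <- noise_spec(contour_jitter_sd = 1, seed = 42)
  expect_identical(perturb_frame(fr, n, 10), perturb_frame(fr, n, 10))
  expect_false(identical(perturb_frame(fr, n, 10), fr))
})

test_that("contour jitter flips a bounded number of boundary pixels", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  fr <- render_frame(tr, spec, 10)
  out <- perturb_frame(fr$rgb, noise_spec(contour_jitter_sd = 1, seed = 1), 10)
  flipped <- sum(apply(abs(out - fr$rgb), c(1, 2), max) > 0.05)
  boundary_len <- nrow(extract_contour(matrix(as.integer(fr$parts > 0),
                                              nrow(fr$parts))))
  # oracle: count of changed pixels, bounded by the boundary length x 3 sd
  expect_gt(flipped, 0)
  expect_lt(flipped, 3 * 1 * boundary_len)
  # the silhouette area changes by far less than the flip budget
  area_change <- abs(sum(apply(out, c(1, 2), max) > 0.75) -
                     sum(apply(fr$rgb, c(1, 2), max) > 0.75))
  expect_lt(area_change, 0.05 * 3 * boundary_len)
})
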