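test_that("undistortion is the identity with zero coefficients", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  fr <- render_frame(tr, spec, 3)$rgb
  expect_identical(undistort_frame(fr, NULL), fr)
  expect_identical(undistort_frame(fr, distortion_coeffs()), fr)
})

test_that("pure radial distortion of a straight line is inverted", {
  co <- distortion_coeffs(k1 = -0.2, center = c(320, 240), focal = 400)
  line <- cbind(seq(40, 600, by = 10), 100)       # horizontal off-centre line
  bent <- gait2d:::distort_points(line, co)
  expect_gt(diff(range(bent[, 2])), 1)            # visibly curved
  straight <- undistort_points(bent, co)
  expect_lt(max(abs(straight - line)), 1e-6)      # sub-pixel residual
})

test_that("compute_scale follows the stated examples and homogeneity", {
  marker <- function(extent_px) list(contour = cbind(c(1, extent_px), c(1, 5)))
  expect_equal(compute_scale(250, marker(250)), 1)
  expect_equal(compute_scale(260, marker(130)), 2)
  expect_error(compute_scale(250, marker(1)),
               class = "gait2d_degenerate_marker")
  # homogeneity: scaling the marker by s scales mm/px by ~1/s
  m1 <- list(contour = cbind(c(10, 90), c(1, 5)))
  m3 <- list(contour = cbind(3 * c(10, 90), c(1, 5)))
  expect_equal(compute_scale(240, m3) * 3 / compute_scale(240, m1), 1,
               tolerance = 0.02)
})

test_that("background-only frames yield the no-subject signal", {
  spec <- tiny_spec()
  bgf <- render_background(spec)
  bg <- background_model(bgf)
  expect_error(segment_foreground(bgf, bg), class = "gait2d_no_subject")
})

test_that("segmentation recovers the renderer silhouette", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  fr <- render_frame(tr, spec, 15)
  bg <- background_model(render_background(spec))
  sil <- segment_foreground(fr$rgb, bg)
  truth_mask <- fr$parts > 0
  inter <- sum(sil$mask > 0 & truth_mask)
  union <- sum(sil$mask > 0 | truth_mask)
  expect_gte(inter / union, 0.95)                       # IoU invariant
  expect_lte(abs(sil$area - sum(truth_mask)) / sum(truth_mask), 0.02)
  # a small uniform brightness change within tolerance leaves it unchanged
  dim_fr <- fr$rgb * 0.95
  sil2 <- segment_foreground(dim_fr, bg)
  expect_identical(sil2$mask, sil$mask)
})

test_that("white-filter extraction matches the renderer's garment masks", {
  spec <- tiny_spec()
  tr <- generate_gait_trajectory(spec)
  fr <- render_frame(tr, spec, 15)
  bg <- background_model(render_background(spec))
  sil <- segment_foreground(fr$rgb, bg)
  blobs <- extract_garment_markers(fr$rgb, sil)
  white <- matrix(as.integer(fr$parts %in% c(4L, 5L, 8L)), nrow(fr$parts))
  n_true <- sum(tabulate(EBImage::bwlabel(white)[EBImage::bwlabel(white) > 0]) >= 50)
  expect_equal(length(blobs), n_true)
  expect_gte(length(blobs), 2)
  # no white pixels -> error signal
  skin_only <- fr$rgb
  for (c in 1:3) {
    pl <- skin_only[, , c]
    pl[fr$parts %in% c(4L, 5L, 8L)] <- c(0.85, 0.55, 0.45)[c]
    skin_only[, , c] <- pl
  }
  expect_error(extract_garment_markers(skin_only, sil),
               class = "gait2d_no_markers")
  # a min-area larger than every blob -> error signal
  expect_error(extract_garment_markers(fr$rgb, sil, min_area = 1e6),
               class = "gait2d_no_markers")
})

test_that("marker labelling follows the height and prediction rules", {
  blob <- function(cx, cy) list(centroid = c(cx, cy), area = 100,
                                pixels = cbind(cx, cy),
                                contour = cbind(cx, cy))
  # pelvis = highest centroid
  lab <- label_markers(list(blob(400, 210), blob(300, 600), blob(520, 200)))
  expect_equal(lab$pelvis$centroid, c(300, 600))
  # nearest-prediction assignment, via brute force over both assignments
  st <- foot_tracker_state()
  st <- update_foot_state(st, list(merged = FALSE,
                                   foot_fg = blob(396, 58), foot_bg = blob(524, 62)), 1)
  st <- update_foot_state(st, list(merged = FALSE,
                                   foot_fg = blob(398, 59), foot_bg = blob(522, 61)), 2)
  blobs <- list(blob(300, 600), blob(518, 59), blob(402, 61))
  lab2 <- label_markers(blobs, st, frame = 3)
  p_fg <- c(400, 60); p_bg <- c(520, 60)
  cands <- list(c(2, 3), c(3, 2))
  tot <- vapply(cands, function(a)
    sqrt(sum((blobs[[a[1]]]$centroid - p_fg)^2)) +
    sqrt(sum((blobs[[a[2]]]$centroid - p_bg)^2)), numeric(1))
  best <- cands[[which.min(tot)]]
  expect_equal(lab2$foot_fg$centroid, blobs[[best[1]]]$centroid)
  expect_equal(lab2$foot_bg$centroid, blobs[[best[2]]]$centroid)
  expect_false(lab2$merged)
  # a single foot blob under both predictions is shared and flagged merged
  lab3 <- label_markers(list(blob(300, 600), blob(460, 60)), st, frame = 3)
  expect_true(lab3$merged)
  expect_equal(lab3$foot_fg$centroid, lab3$foot_bg$centroid)
  # cold start: the foreground foot is the most advanced blob
  lab4 <- label_markers(list(blob(300, 600), blob(100, 60), blob(200, 60)))
  expect_equal(lab4$foot_fg$centroid, c(200, 60))
  # pelvis blob below the predicted feet raises a labelling warning
  st_hi <- foot_tracker_state()
  st_hi <- update_foot_state(st_hi, list(merged = FALSE,
                                         foot_fg = blob(100, 700),
                                         foot_bg = blob(200, 710)), 1)
  lab5 <- label_markers(list(blob(300, 600), blob(100, 400), blob(200, 410)),
                        st_hi, frame = 2)
  expect_gt(length(lab5$warnings), 0)
})

test_that("contour extraction matches perimeter oracles", {
  m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
  ct <- extract_contour(m)
  expect_equal(nrow(ct), 36)                      # 10x10 square boundary
  # rasterized disk: contour length within 10% of 2*pi*r
  r <- 30; W <- 80
  xy <- expand.grid(x = 1:W, y = 1:W)
  d <- matrix(as.integer((xy$x - 40)^2 + (xy$y - 40)^2 <= r^2), W, W)
  len <- gait2d:::contour_length(extract_contour(d))
  expect_lt(abs(len - 2 * pi * r) / (2 * pi * r), 0.1)
  # holes are ignored: only the outer boundary is traced
  h <- m; h[9:12, 9:12] <- 0L
  expect_equal(nrow(extract_contour(h)), 36)
  expect_error(extract_contour(matrix(0L, 5, 5)), class = "gait2d_empty_mask")
})
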