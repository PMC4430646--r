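test_that("degenerate distance series raise the no-events error", {
  expect_error(detect_gait_events(rep(0, 50), rep(5, 50), fps = 50),
               class = "gait2d_no_events")
})

test_that("triangular distance peaks are found at their apex frames", {
  # brute-force oracle: apex of each triangle by sliding-window argmax
  tri <- function(n, peak, amp) {
    x <- numeric(n)
    for (i in 1:n) x[i] <- amp - abs(i - peak)
    x
  }
  d <- pmax(tri(120, 10, 60), tri(120, 70, 60))
  oracle <- which(vapply(2:119, function(i)
    d[i] > d[i - 1] && d[i] > d[i + 1], logical(1))) + 1
  ev <- detect_gait_events(rep(0, 120), d, fps = 50, min_prominence = 5)
  expect_equal(ev$heel_strikes, oracle)
  expect_equal(ev$heel_strikes, c(10, 70))
})

test_that("plateau maxima resolve to their first frame", {
  d <- c(0, 10, 40, 40, 40, 10, 0, 10, 45, 10, 0)
  ev <- detect_gait_events(rep(0, 11), d, fps = 50, min_separation_frac = 0)
  expect_equal(ev$heel_strikes, c(3, 9))
})

test_that("detected events match renderer ground truth within 1 frame", {
  tr <- get_trial("comfortable")
  truth <- tr$truth; res <- tr$res
  for (hs in res$events$heel_strikes)
    expect_lte(min(abs(truth$events$hs_fg - hs)), 1)
  for (to in res$events$toe_offs)
    expect_lte(min(abs(truth$events$to_fg - to)), 1)
  # parity: within a contiguous trial HS and TO counts differ by <= 1
  expect_lte(abs(length(res$events$heel_strikes) -
                 length(res$events$toe_offs)), 1)
})

test_that("spatiotemporal parameters follow their definitions", {
  ev <- structure(list(heel_strikes = c(1, 61),
                       cycles = cbind(start = 1, end = 61), fps = 50),
                  class = "gait_events")
  foot_x <- seq(0, 1500, length.out = 61)
  p <- spatiotemporal_params(ev, foot_x, mm_per_px = 1, fps = 50)
  expect_equal(p$stride_time, 1.2)
  expect_equal(p$cadence, 100)
  expect_equal(p$stride_length, 1.5)
  expect_equal(p$walking_speed, 1.25)
  # consistency invariant
  expect_equal(p$walking_speed, p$stride_length / p$stride_time,
               tolerance = 1e-9)
  ev1 <- structure(list(heel_strikes = 5,
                        cycles = matrix(integer(0), 0, 2), fps = 50),
                   class = "gait_events")
  expect_error(spatiotemporal_params(ev1, foot_x, 1, 50),
               class = "gait2d_no_events")
})

test_that("stride length scales linearly with mm/px; timing does not", {
  ev <- structure(list(heel_strikes = c(1, 61),
                       cycles = cbind(start = 1, end = 61), fps = 50),
                  class = "gait_events")
  foot_x <- seq(0, 1500, length.out = 61)
  p1 <- spatiotemporal_params(ev, foot_x, 1, 50)
  p3 <- spatiotemporal_params(ev, foot_x, 3, 50)
  expect_equal(p3$stride_length, 3 * p1$stride_length)
  expect_equal(p3$stride_time, p1$stride_time)
  expect_equal(p3$cadence, p1$cadence)
})

test_that("2x frame duplication changes stride time by at most one frame", {
  tr <- get_trial("comfortable")
  lmk <- tr$truth$frames
  d_p <- lmk$pelvis_cx; d_f <- lmk$foot_fg_cx
  ev1 <- detect_gait_events(d_p, d_f, fps = 50)
  p1 <- spatiotemporal_params(ev1, d_f, 1, 50)
  up <- function(x) rep(x, each = 2)
  ev2 <- detect_gait_events(up(d_p), up(d_f), fps = 100)
  p2 <- spatiotemporal_params(ev2, up(d_f), 1, 100)
  expect_lte(abs(p1$stride_time - p2$stride_time), 1 / 50)
})
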