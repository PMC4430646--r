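# Synthetic articulated-walker generator: ground-truthed gait trajectories
# and rendered image sequences emulating the recording protocol (lateral
# camera, homogeneous blue background, white ankle socks and underwear,
# 50 fps). The walker is a 2D sagittal linkage: pelvis (with tilt), thigh,
# shank and flat-bottomed foot per leg, the background leg phase-shifted
# by half a cycle and occluded by the foreground leg.

# ---- joint curve templates ------------------------------------------------

#' Evaluate a periodic joint-angle curve
#'
#' Curves are truncated Fourier series over one gait cycle:
#' `a0 + sum_k a_k cos(2 pi k phase) + b_k sin(2 pi k phase)`.
#'
#' @param curve list with fields `a0`, `a`, `b` (numeric coefficient
#'   vectors, possibly empty).
#' @param phase gait-cycle fraction(s), any real (periodic).
#' @return angle(s) in degrees.
#' @export
eval_joint_curve <- function(curve, phase) {
  out <- rep(curve$a0, length.out = length(phase))
  K <- max(length(curve$a), length(curve$b))
  for (k in seq_len(K)) {
    ak <- if (k <= length(curve$a)) curve$a[k] else 0
    bk <- if (k <= length(curve$b)) curve$b[k] else 0
    out <- out + ak * cos(2 * pi * k * phase) + bk * sin(2 * pi * k * phase)
  }
  out
}

#' Default joint-angle curve templates
#'
#' Smooth periodic templates qualitatively matching normal adult sagittal
#' gait: hip flexion about +30 deg around heel strike down to about -10 deg
#' in terminal stance; knee flexion with a small loading-response bump and
#' a ~60 deg swing peak; ankle dorsi/plantarflexion between about -13 and
#' +10 deg with plantarflexion at push-off; pelvic tilt of small (< 5 deg)
#' amplitude at twice the stride frequency. The exact coefficients are a
#' fixture of the generator, not a physiological claim.
#'
#' @return named list of curves (`hip`, `knee`, `ankle`, `pelvic_tilt`)
#'   consumable by [eval_joint_curve()]. Flexion / dorsiflexion positive.
#' @export
default_joint_curves <- function() {
  list(
    hip = list(a0 = 10, a = c(20, 2), b = c(3, 0)),
    knee = list(a0 = 20.2471, a = c(-3.6614, -13.2662, 2.4608),
                b = c(-18.7719, 8.5814, 4.234)),
    ankle = list(a0 = 0.7864, a = c(-1.6101, 1.7477, -3.3464),
                 b = c(5.0219, -6.7702, 0.7623)),
    pelvic_tilt = list(a0 = 1, a = c(0, 0), b = c(0, 2))
  )
}

# ---- specs ----------------------------------------------------------------

#' Specification of a synthetic gait trial
#'
#' Defaults emulate the nominal recording protocol: 1280 x 720 frames at
#' 50 fps, subject walking left to right at comfortable speed, roughly
#' 3 mm per pixel. Use [speed_preset()] for the slow / comfortable / fast
#' walking conditions.
#'
#' @param fps frame rate, frames/s.
#' @param image_size `c(width, height)` in px.
#' @param mm_per_px spatial scale of the rendering, mm per pixel.
#' @param walking_speed m/s.
#' @param stride_time s per gait cycle.
#' @param n_cycles trial duration in gait cycles (fractional allowed).
#' @param segment_lengths named list, mm: `pelvis_depth`, `thigh`, `shank`,
#'   `foot`.
#' @param joint_curves list of Fourier curves, see [default_joint_curves()].
#' @param phase_offset_background_leg cycle fraction between the legs.
#' @param start_phase gait-cycle phase of the foreground leg at frame 1.
#' @param start_x_mm horizontal position of the hip at frame 1, mm.
#' @param pelvis_shape_amp_mm amplitude of the cyclic pelvis-marker shape
#'   change (posterior edge excursion), emulating the apparent shape change
#'   of the worn garment over the cycle.
#' @param seed integer seed for all randomness attached to this trial.
#' @return object of class `gait_spec`.
#' @export
gait_spec <- function(fps = 50,
                      image_size = c(1280, 720),
                      mm_per_px = 3,
                      walking_speed = 1.25,
                      stride_time = 1.2,
                      n_cycles = 1.5,
                      segment_lengths = list(pelvis_depth = 240, thigh = 410,
                                             shank = 400, foot = 240),
                      joint_curves = default_joint_curves(),
                      phase_offset_background_leg = 0.5,
                      start_phase = 0.9,
                      start_x_mm = 300,
                      pelvis_shape_amp_mm = 2.5,
                      seed = 1L) {
  stopifnot(fps > 0, stride_time > 0, walking_speed > 0, n_cycles > 0,
            mm_per_px > 0, length(image_size) == 2, all(image_size >= 16))
  lens <- segment_lengths
  stopifnot(all(unlist(lens[c("pelvis_depth", "thigh", "shank", "foot")]) > 0))
  stride_mm <- walking_speed * stride_time * 1000
  if (stride_mm > 2.4 * (lens$thigh + lens$shank))
    gait2d_stop("gait2d_nonphysical_spec",
                sprintf("stride length %.0f mm exceeds leg reach", stride_mm))
  structure(list(fps = fps, image_size = as.integer(image_size),
                 mm_per_px = mm_per_px, walking_speed = walking_speed,
                 stride_time = stride_time, n_cycles = n_cycles,
                 segment_lengths = lens, joint_curves = joint_curves,
                 phase_offset_background_leg = phase_offset_background_leg,
                 start_phase = start_phase, start_x_mm = start_x_mm,
                 pelvis_shape_amp_mm = pelvis_shape_amp_mm,
                 seed = as.integer(seed)),
            class = "gait_spec")
}

#' Walking-speed presets
#'
#' Slow, comfortable and fast walking conditions (speed and stride time
#' covary as in adult overground walking).
#'
#' @param speed one of `"slow"`, `"comfortable"`, `"fast"`.
#' @param ... further arguments passed to [gait_spec()].
#' @return a [gait_spec()].
#' @export
speed_preset <- function(speed = c("comfortable", "slow", "fast"), ...) {
  speed <- match.arg(speed)
  par <- switch(speed,
    slow = list(walking_speed = 0.93, stride_time = 1.40),
    comfortable = list(walking_speed = 1.25, stride_time = 1.20),
    fast = list(walking_speed = 1.70, stride_time = 1.00))
  do.call(gait_spec, c(par, list(...)))
}

#' Specification of rendering noise
#'
#' @param contour_jitter_sd sd (px) controlling random flips of
#'   silhouette-boundary pixels.
#' @param illumination_gradient fractional left-to-right multiplicative
#'   brightness ramp.
#' @param hue_drift hue shift amplitude across the image, degrees.
#' @param blur_radius Gaussian blur sigma, px (0 = none).
#' @param seed integer seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(contour_jitter_sd = 0, illumination_gradient = 0,
                       hue_drift = 0, blur_radius = 0, seed = 1L) {
  stopifnot(contour_jitter_sd >= 0, illumination_gradient >= 0,
            hue_drift >= 0, blur_radius >= 0)
  structure(list(contour_jitter_sd = contour_jitter_sd,
                 illumination_gradient = illumination_gradient,
                 hue_drift = hue_drift, blur_radius = blur_radius,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# ---- walker geometry ------------------------------------------------------

# Fixed body shape parameters (mm), relative to segment frames.
walker_shape <- function(spec) {
  lens <- spec$segment_lengths
  foot <- lens$foot
  # flat-bottomed foot polygon, origin at LM (ankle); length = lens$foot,
  # LM at ~23% of foot length from the heel
  heel <- -0.23 * foot; toe <- 0.77 * foot
  foot_poly <- cbind(
    x = c(heel, toe, toe, 0.40 * foot, 0.10 * foot, -0.125 * foot, heel),
    y = c(-75, -75, -45, -15, 20, 20, -35))
  hw <- lens$pelvis_depth / 2          # pelvis marker halfwidth (120 mm)
  pelvis_quad <- cbind(x = c(-hw, hw, hw - 20, -hw + 20),
                       y = c(140, 140, -40, -40))
  list(foot_poly = foot_poly,
       foot_centroid = polygon_centroid(foot_poly),
       pelvis_quad = pelvis_quad,
       shank_r = 50, thigh_r = 70, trunk_r = 95,
       trunk_top = 360, trunk_bottom = 60,
       ankle_height = 115, vert_osc = 10)
}

# Continuous-time walker state in mm. phase_fg = foreground-leg phase.
# Returns absolute segment orientations (deg, CCW) and joint positions.
walker_state <- function(spec, t, phase_fg) {
  jc <- spec$joint_curves
  lens <- spec$segment_lengths
  sh <- walker_shape(spec)
  hip_h <- sh$ankle_height + lens$thigh + lens$shank
  tilt <- eval_joint_curve(jc$pelvic_tilt, phase_fg)
  hip <- c(spec$start_x_mm + spec$walking_speed * 1000 * t,
           hip_h + sh$vert_osc * sin(4 * pi * phase_fg))
  leg <- function(ph) {
    th_f <- eval_joint_curve(jc$hip, ph) + tilt
    th_s <- th_f - eval_joint_curve(jc$knee, ph)
    th_foot <- th_s + eval_joint_curve(jc$ankle, ph)
    u <- function(a) c(sin(a * pi / 180), -cos(a * pi / 180))
    K <- hip + lens$thigh * u(th_f)
    A <- K + lens$shank * u(th_s)
    list(theta_f = th_f, theta_s = th_s, theta_foot = th_foot,
         knee = K, ankle = A, phase = ph %% 1)
  }
  list(hip = hip, tilt = tilt,
       fg = leg(phase_fg),
       bg = leg(phase_fg + spec$phase_offset_background_leg),
       pshape = spec$pelvis_shape_amp_mm * sin(2 * pi * phase_fg))
}

# mm-space centroids of the garment markers for a walker state
marker_centroids_mm <- function(spec, st) {
  sh <- walker_shape(spec)
  foot_c <- function(leg) {
    rotate_points(matrix(sh$foot_centroid, 1, 2), leg$theta_foot)[1, ] + leg$ankle
  }
  pq <- sh$pelvis_quad
  pq[c(1, 4), 1] <- pq[c(1, 4), 1] - st$pshape   # posterior shape mode
  pq <- rotate_points(pq, st$tilt) ; pq <- sweep(pq, 2, st$hip, `+`)
  list(foot_fg = foot_c(st$fg), foot_bg = foot_c(st$bg),
       pelvis = polygon_centroid(pq), pelvis_quad = pq,
       pl = rotate_points(matrix(c(0, 140), 1, 2), st$tilt)[1, ] + st$hip,
       pp = pq[1, ])
}

# ---- trajectory generation ------------------------------------------------

#' Generate a ground-truthed synthetic gait trajectory
#'
#' Produces the full kinematic time history of the articulated walker:
#' per-frame joint angles and landmark positions (px), true heel-strike /
#' toe-off frames per side, and true spatiotemporal parameters. Events are
#' located on a 20x-oversampled time grid as the interior local extrema of
#' the horizontal foot-pelvis centroid distance, then snapped to the
#' nearest frame, so that on clean data the event detector used by the
#' pipeline is exact by construction.
#'
#' @param spec a [gait_spec()].
#' @return object of class `gait_truth`: list with `spec`, `n_frames`,
#'   `frames` (per-frame data.frame: angles in deg, landmark and centroid
#'   coordinates in px, mm-space pose columns used by the renderer),
#'   `events` (frame indices per side) and `params` (true cadence
#'   steps/min, speed m/s, stride time s, stride length m).
#' @export
generate_gait_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  fps <- spec$fps; Tc <- spec$stride_time
  n <- floor(spec$n_cycles * Tc * fps) + 1L
  mmpp <- spec$mm_per_px
  jc <- spec$joint_curves

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- (i - 1) / fps
    ph <- spec$start_phase + t / Tc
    st <- walker_state(spec, t, ph)
    mc <- marker_centroids_mm(spec, st)
    rows[[i]] <- data.frame(
      frame = i, time_s = t, phase = ph %% 1,
      hip_deg = eval_joint_curve(jc$hip, ph),
      knee_deg = eval_joint_curve(jc$knee, ph),
      ankle_deg = eval_joint_curve(jc$ankle, ph),
      pelvic_tilt_deg = st$tilt,
      lm_x = st$fg$ankle[1] / mmpp, lm_y = st$fg$ankle[2] / mmpp,
      le_x = st$fg$knee[1] / mmpp, le_y = st$fg$knee[2] / mmpp,
      gt_x = st$hip[1] / mmpp, gt_y = st$hip[2] / mmpp,
      pl_x = mc$pl[1] / mmpp, pl_y = mc$pl[2] / mmpp,
      pp_x = mc$pp[1] / mmpp, pp_y = mc$pp[2] / mmpp,
      foot_fg_cx = mc$foot_fg[1] / mmpp, foot_fg_cy = mc$foot_fg[2] / mmpp,
      foot_bg_cx = mc$foot_bg[1] / mmpp, foot_bg_cy = mc$foot_bg[2] / mmpp,
      pelvis_cx = mc$pelvis[1] / mmpp, pelvis_cy = mc$pelvis[2] / mmpp,
      hip_mm_x = st$hip[1], hip_mm_y = st$hip[2],
      theta_f_fg = st$fg$theta_f, theta_s_fg = st$fg$theta_s,
      theta_foot_fg = st$fg$theta_foot,
      theta_f_bg = st$bg$theta_f, theta_s_bg = st$bg$theta_s,
      theta_foot_bg = st$bg$theta_foot,
      pshape_mm = st$pshape)
  }
  frames <- do.call(rbind, rows)

  # events from the oversampled continuous trajectory
  over <- 20L
  tt <- seq(0, (n - 1) / fps, by = 1 / (fps * over))
  d_side <- function(side) {
    vapply(tt, function(t) {
      st <- walker_state(spec, t, spec$start_phase + t / Tc)
      mc <- marker_centroids_mm(spec, st)
      mc[[side]][1] - mc$pelvis[1]
    }, numeric(1))
  }
  extrema_frames <- function(d, minima = FALSE) {
    if (minima) d <- -d
    k <- which(diff(sign(diff(d))) < 0) + 1L   # interior local maxima
    sort(unique(as.integer(round((tt[k]) * fps)) + 1L))
  }
  d_fg <- d_side("foot_fg"); d_bg <- d_side("foot_bg")
  events <- list(hs_fg = extrema_frames(d_fg), to_fg = extrema_frames(d_fg, TRUE),
                 hs_bg = extrema_frames(d_bg), to_bg = extrema_frames(d_bg, TRUE))

  params <- list(cadence_steps_min = 120 / Tc,
                 walking_speed_ms = spec$walking_speed,
                 stride_time_s = Tc,
                 stride_length_m = spec$walking_speed * Tc)

  structure(list(spec = spec, n_frames = n, frames = frames,
                 events = events, params = params),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %d frames @ %g fps, stride %.2f s, speed %.2f m/s\n",
              x$n_frames, x$spec$fps, x$params$stride_time_s,
              x$params$walking_speed_ms))
  cat("  foreground heel strikes at frames:",
      paste(x$events$hs_fg, collapse = ", "), "\n")
  invisible(x)
}

# ---- rendering ------------------------------------------------------------

# part id codes used by the renderer
PART_TRUNK <- 1L; PART_THIGH_BG <- 2L; PART_SHANK_BG <- 3L; PART_FOOT_BG <- 4L
PART_PELVIS <- 5L; PART_THIGH_FG <- 6L; PART_SHANK_FG <- 7L; PART_FOOT_FG <- 8L

render_colors <- function() {
  conv <- function(h, s, v) as.vector(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
  list(bg = conv(240 / 360, 0.75, 0.65),
       skin = conv(25 / 360, 0.45, 0.85),
       white = conv(0, 0.02, 0.98))
}

# paint a part (pixel list) into the integer part map
paint_part <- function(parts, pts, id) {
  if (nrow(pts)) parts[cbind(pts[, 1], pts[, 2])] <- id
  parts
}

# Render one walker state into a part map + RGB array.
render_state <- function(spec, st) {
  W <- spec$image_size[1]; H <- spec$image_size[2]
  mmpp <- spec$mm_per_px
  sh <- walker_shape(spec)
  parts <- matrix(0L, W, H)

  leg_parts <- function(parts, leg, foot_id, shank_id, thigh_id) {
    hip_px <- st$hip / mmpp
    knee_px <- leg$knee / mmpp; ank_px <- leg$ankle / mmpp
    parts <- paint_part(parts,
      rasterize_capsule(hip_px, knee_px, sh$thigh_r / mmpp, W, H), thigh_id)
    parts <- paint_part(parts,
      rasterize_capsule(knee_px, ank_px, sh$shank_r / mmpp, W, H), shank_id)
    fp <- rotate_points(sh$foot_poly, leg$theta_foot)
    fp <- sweep(fp, 2, leg$ankle, `+`) / mmpp
    paint_part(parts, rasterize_polygon(fp, W, H), foot_id)
  }

  trunk_a <- (st$hip + c(0, sh$trunk_bottom)) / mmpp
  trunk_b <- (st$hip + c(0, sh$trunk_top)) / mmpp
  parts <- paint_part(parts,
    rasterize_capsule(trunk_a, trunk_b, sh$trunk_r / mmpp, W, H), PART_TRUNK)
  parts <- leg_parts(parts, st$bg, PART_FOOT_BG, PART_SHANK_BG, PART_THIGH_BG)
  pq <- sh$pelvis_quad
  pq[c(1, 4), 1] <- pq[c(1, 4), 1] - st$pshape
  pq <- sweep(rotate_points(pq, st$tilt), 2, st$hip, `+`) / mmpp
  parts <- paint_part(parts, rasterize_polygon(pq, W, H), PART_PELVIS)
  parts <- leg_parts(parts, st$fg, PART_FOOT_FG, PART_SHANK_FG, PART_THIGH_FG)
  parts
}

parts_to_rgb <- function(parts) {
  cols <- render_colors()
  W <- nrow(parts); H <- ncol(parts)
  arr <- array(0, c(W, H, 3))
  skin <- parts %in% c(PART_TRUNK, PART_THIGH_BG, PART_SHANK_BG,
                       PART_THIGH_FG, PART_SHANK_FG)
  white <- parts %in% c(PART_FOOT_BG, PART_PELVIS, PART_FOOT_FG)
  for (c in 1:3) {
    plane <- matrix(cols$bg[c], W, H)
    plane[skin] <- cols$skin[c]
    plane[white] <- cols$white[c]
    arr[, , c] <- plane
  }
  arr
}

#' Render one frame of a synthetic trial
#'
#' @param truth a [generate_gait_trajectory()] result.
#' @param spec the matching [gait_spec()].
#' @param i frame index (row of `truth$frames`).
#' @return list with `rgb` (width x height x 3 array, values in `[0, 1]`,
#'   y-up orientation) and `parts` (integer part-id matrix: 0 background,
#'   skin and white garment part codes; see `gait2d:::PART_PELVIS` etc.),
#'   from which silhouette and white-garment ground-truth masks derive.
#' @export
render_frame <- function(truth, spec, i) {
  r <- truth$frames[i, ]
  st <- list(hip = c(r$hip_mm_x, r$hip_mm_y), tilt = r$pelvic_tilt_deg,
             fg = list(theta_f = r$theta_f_fg, theta_s = r$theta_s_fg,
                       theta_foot = r$theta_foot_fg,
                       knee = c(r$le_x, r$le_y) * spec$mm_per_px,
                       ankle = c(r$lm_x, r$lm_y) * spec$mm_per_px),
             bg = NULL, pshape = r$pshape_mm)
  # background-leg joints are not stored per frame; recompute
  full <- walker_state(spec, r$time_s, spec$start_phase + r$time_s / spec$stride_time)
  st$bg <- full$bg
  parts <- render_state(spec, st)
  list(rgb = parts_to_rgb(parts), parts = parts)
}

#' Render a whole trial plus the static reference frame
#'
#' @inheritParams render_frame
#' @param frames which frame indices to render (default all).
#' @return list with `frames` (list of [render_frame()] results), `static`
#'   (static reference render), and `out_of_view` (frame indices whose
#'   walker extends beyond the image).
#' @export
render_frames <- function(truth, spec, frames = seq_len(truth$n_frames)) {
  out <- lapply(frames, function(i) render_frame(truth, spec, i))
  oov <- frames[vapply(out, function(f) frame_touches_border(f$parts),
                       logical(1))]
  if (length(oov))
    warning("walker touches the image border in frames: ",
            paste(oov, collapse = ", "))
  list(frames = out, static = render_static(spec), out_of_view = oov)
}

frame_touches_border <- function(parts) {
  W <- nrow(parts); H <- ncol(parts)
  any(parts[1, ] > 0) || any(parts[W, ] > 0) ||
    any(parts[, 1] > 0) || any(parts[, H] > 0)
}

#' Render the static reference frame (upright neutral pose, centred)
#'
#' @param spec a [gait_spec()].
#' @return list with `rgb`, `parts`, and `landmarks` (true static LM, LE,
#'   GT and foot-length in px, as an operator would identify them).
#' @export
render_static <- function(spec) {
  sh <- walker_shape(spec)
  lens <- spec$segment_lengths
  hip_h <- sh$ankle_height + lens$thigh + lens$shank
  cx <- spec$image_size[1] * spec$mm_per_px / 2
  st <- list(hip = c(cx, hip_h), tilt = 0,
             fg = list(theta_f = 0, theta_s = 0, theta_foot = 0,
                       knee = c(cx, hip_h - lens$thigh),
                       ankle = c(cx, sh$ankle_height)),
             pshape = 0)
  st$bg <- st$fg
  parts <- render_state(spec, st)
  mmpp <- spec$mm_per_px
  list(rgb = parts_to_rgb(parts), parts = parts,
       landmarks = list(LM = st$fg$ankle / mmpp,
                        LE = st$fg$knee / mmpp,
                        GT = st$hip / mmpp,
                        foot_length_mm = lens$foot))
}

#' Render the empty background frame
#' @param spec a [gait_spec()].
#' @return width x height x 3 RGB array of the uniform blue background.
#' @export
render_background <- function(spec) {
  cols <- render_colors()
  W <- spec$image_size[1]; H <- spec$image_size[2]
  arr <- array(0, c(W, H, 3))
  for (c in 1:3) arr[, , c] <- cols$bg[c]
  arr
}

# ---- noise ----------------------------------------------------------------

# fast vectorized hsv -> rgb for matrices of h (fraction), s, v
hsv_to_rgb_mat <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Apply acquisition noise to a rendered frame
#'
#' Deterministic given `noise$seed` and `frame_index`: boundary-local
#' pixel flips (contour jitter), a smooth multiplicative illumination ramp,
#' a smooth hue-shift field and optional Gaussian blur.
#'
#' @param rgb width x height x 3 array in `[0, 1]`.
#' @param noise a [noise_spec()].
#' @param frame_index integer; combined with the seed so that each frame
#'   of a trial gets an independent, reproducible stream.
#' @return perturbed array, same shape.
#' @export
perturb_frame <- function(rgb, noise, frame_index = 1L) {
  stopifnot(inherits(noise, "noise_spec"))
  W <- dim(rgb)[1]; H <- dim(rgb)[2]
  if (noise$contour_jitter_sd > 0) {
    set.seed((as.numeric(noise$seed) * 131071 + as.numeric(frame_index) * 7919) %%
               .Machine$integer.max)
    bg_col <- rgb[1, 1, ]
    dist <- pmax(abs(rgb[, , 1] - bg_col[1]),
                 pmax(abs(rgb[, , 2] - bg_col[2]), abs(rgb[, , 3] - bg_col[3])))
    fg <- dist > 0.1
    shft <- function(m, dx, dy) {
      out <- matrix(FALSE, W, H)
      xs <- max(1, 1 + dx):min(W, W + dx); ys <- max(1, 1 + dy):min(H, H + dy)
      out[xs, ys] <- m[xs - dx, ys - dy]
      out
    }
    nb_any <- shft(fg, 1, 0) | shft(fg, -1, 0) | shft(fg, 0, 1) | shft(fg, 0, -1)
    nb_all <- shft(fg, 1, 0) & shft(fg, -1, 0) & shft(fg, 0, 1) & shft(fg, 0, -1)
    b_fg <- which(fg & !nb_all)          # foreground boundary pixels
    b_bg <- which(!fg & nb_any)          # background pixels touching fg
    erode <- b_fg[abs(rnorm(length(b_fg), 0, noise$contour_jitter_sd)) > 1]
    dilate <- b_bg[abs(rnorm(length(b_bg), 0, noise$contour_jitter_sd)) > 1]
    # dilated pixels copy the colour of their first foreground 4-neighbour
    nmax <- W * H
    pick <- function(cand, ok) ifelse(ok & fg[pmin(pmax(cand, 1L), nmax)],
                                      cand, NA_integer_)
    src <- pick(dilate - 1L, dilate > 1L)
    src <- ifelse(is.na(src), pick(dilate + 1L, dilate < nmax), src)
    src <- ifelse(is.na(src), pick(dilate - W, dilate > W), src)
    src <- ifelse(is.na(src), pick(dilate + W, dilate <= nmax - W), src)
    keep <- !is.na(src)
    dilate <- dilate[keep]; src <- src[keep]
    for (c in 1:3) {
      orig <- rgb[, , c]
      plane <- orig
      plane[erode] <- bg_col[c]
      plane[dilate] <- orig[src]
      rgb[, , c] <- plane
    }
  }
  if (noise$illumination_gradient > 0) {
    ramp <- 1 + noise$illumination_gradient * ((seq_len(W) - 0.5) / W - 0.5)
    for (c in 1:3) rgb[, , c] <- pmin(1, rgb[, , c] * ramp)
  }
  if (noise$hue_drift > 0) {
    hsvm <- grDevices::rgb2hsv(rbind(as.vector(rgb[, , 1]),
                                     as.vector(rgb[, , 2]),
                                     as.vector(rgb[, , 3])), maxColorValue = 1)
    field <- (noise$hue_drift / 360) * ((seq_len(W) - 0.5) / W - 0.5)
    h <- matrix(hsvm[1, ], W, H) + field
    out <- hsv_to_rgb_mat(h, matrix(hsvm[2, ], W, H), matrix(hsvm[3, ], W, H))
    rgb[, , 1] <- out$r; rgb[, , 2] <- out$g; rgb[, , 3] <- out$b
  }
  if (noise$blur_radius > 0) {
    for (c in 1:3)
      rgb[, , c] <- as.matrix(EBImage::gblur(EBImage::Image(rgb[, , c]),
                                             sigma = noise$blur_radius))
  }
  rgb
}

#' Apply noise to a list of frames
#' @param frames list of RGB arrays (or [render_frame()] results).
#' @param noise a [noise_spec()].
#' @return list of perturbed RGB arrays.
#' @export
perturb_frames <- function(frames, noise) {
  lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (is.list(f)) f <- f$rgb
    perturb_frame(f, noise, i)
  })
}
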