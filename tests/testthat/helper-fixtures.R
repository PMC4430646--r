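# Shared fixtures. Rendering full trials is the expensive part of the
# suite, so simulated trials (and their pipeline runs) are built once per
# speed preset and cached for the whole session.

.trial_cache <- new.env(parent = emptyenv())

# spec used for validation trials: protocol frame rate, scaled-down frame
trial_spec <- function(speed, seed = 1L) {
  speed_preset(speed, image_size = c(1280, 480), mm_per_px = 3, seed = seed)
}

# simulate a trial (1 px contour jitter) and run the full pipeline once
get_trial <- function(speed, seed = 1L) {
  key <- paste(speed, seed, sep = "_")
  if (!is.null(.trial_cache[[key]])) return(.trial_cache[[key]])
  dir <- file.path(tempdir(), paste0("gait2d_trial_", key))
  spec <- trial_spec(speed, seed)
  sim <- simulate_trial(spec, noise_spec(contour_jitter_sd = 1, seed = seed), dir)
  res <- run_pipeline(dir, out_dir = file.path(dir, "output"))
  .trial_cache[[key]] <- list(dir = dir, spec = spec, truth = sim$truth,
                              res = res)
  .trial_cache[[key]]
}

# small spec for cheap single-frame rendering tests
tiny_spec <- function(...) {
  args <- utils::modifyList(list(image_size = c(640, 360), mm_per_px = 6,
                                 seed = 7L), list(...))
  do.call(gait_spec, args)
}

# ground-truth normalized curve for a joint over a (detected) cycle
truth_curve <- function(truth, cycle, joint) {
  col <- paste0(joint, "_deg")
  x <- truth$frames[[col]][cycle[1]:cycle[2]]
  time_normalize(x, 1, length(x))
}

# render a posed foot marker blob (contour + pixels) for fixture tests
render_foot_blob <- function(theta_deg = 0, ankle_px = c(100, 100),
                             mm_per_px = 1, W = 400, H = 300) {
  sh <- gait2d:::walker_shape(gait_spec())
  fp <- gait2d:::rotate_points(sh$foot_poly, theta_deg) / mm_per_px
  fp <- sweep(fp, 2, ankle_px, `+`)
  px <- gait2d:::rasterize_polygon(fp, W, H)
  mask <- matrix(0L, W, H)
  mask[px] <- 1L
  list(pixels = px, centroid = colMeans(px), area = nrow(px),
       contour = extract_contour(mask),
       bbox = c(range(px[, 1]), range(px[, 2])), mask = mask)
}
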