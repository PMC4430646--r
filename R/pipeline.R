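# End-to-end orchestration: trial simulation to disk, configuration,
# and the full processing pipeline (preprocessing -> events -> calibration
# -> tracking -> kinematics -> comparison metrics), with standard-format
# outputs (CSV/JSON) and a structured run report.

#' Write a complete synthetic trial to a directory
#'
#' Renders and writes the frame sequence, static reference image and
#' background frame as PNG files, an index manifest, an auto-generated
#' landmark sidecar (from ground truth, standing in for operator clicks),
#' and the ground-truth tables. The directory is directly consumable by
#' [run_pipeline()].
#'
#' @param spec a [gait_spec()].
#' @param noise a [noise_spec()].
#' @param dir output directory (created).
#' @return invisibly, a list with `dir` and the `gait_truth` object.
#' @export
simulate_trial <- function(spec, noise = noise_spec(), dir) {
  truth <- generate_gait_trajectory(spec)
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  bg <- perturb_frame(render_background(spec), noise, frame_index = 900001L)
  write_frame_png(bg, file.path(dir, "background.png"))
  st <- render_static(spec)
  write_frame_png(perturb_frame(st$rgb, noise, frame_index = 900002L),
                  file.path(dir, "static.png"))

  files <- character(truth$n_frames)
  oov <- integer(0)
  for (i in seq_len(truth$n_frames)) {
    fr <- render_frame(truth, spec, i)
    if (frame_touches_border(fr$parts)) oov <- c(oov, i)
    files[i] <- sprintf("frames/frame_%04d.png", i)
    write_frame_png(perturb_frame(fr$rgb, noise, i),
                    file.path(dir, files[i]))
  }
  if (length(oov))
    warning("walker touches the image border in frames: ",
            paste(oov, collapse = ", "))

  manifest <- list(fps = spec$fps, width = spec$image_size[1],
                   height = spec$image_size[2], n_frames = truth$n_frames,
                   frames = files, static = "static.png",
                   background = "background.png", seed = spec$seed,
                   noise_seed = noise$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  pl <- lapply(seq_len(truth$n_frames), function(i)
    c(truth$frames$pl_x[i], truth$frames$pl_y[i]))
  names(pl) <- as.character(seq_len(truth$n_frames))
  landmarks <- list(static = list(LM = st$landmarks$LM, LE = st$landmarks$LE,
                                  GT = st$landmarks$GT),
                    PL = pl,
                    foot_length_mm = st$landmarks$foot_length_mm)
  jsonlite::write_json(landmarks, file.path(dir, "landmarks.json"),
                       auto_unbox = TRUE, digits = NA)

  tr <- truth$frames
  write.csv(tr[, c("frame", "time_s", "phase", "hip_deg", "knee_deg",
                   "ankle_deg", "pelvic_tilt_deg")],
            file.path(dir, "truth", "angles.csv"), row.names = FALSE)
  write.csv(tr[, c("frame", "lm_x", "lm_y", "le_x", "le_y", "gt_x", "gt_y",
                   "pl_x", "pl_y", "pp_x", "pp_y", "foot_fg_cx", "foot_fg_cy",
                   "foot_bg_cx", "foot_bg_cy", "pelvis_cx", "pelvis_cy")],
            file.path(dir, "truth", "landmarks.csv"), row.names = FALSE)
  jsonlite::write_json(list(events = truth$events, params = truth$params,
                            mm_per_px = spec$mm_per_px,
                            out_of_view = oov),
                       file.path(dir, "truth", "events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, truth = truth))
}

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the pipeline with their defaults:
#' HSV background-subtraction tolerances, white-filter thresholds and
#' minimum blob area, foot-matcher search grid, Butterworth filter
#' settings, and event-detector debouncing.
#'
#' @param h_tol_deg,s_tol,v_tol background-subtraction tolerances.
#' @param s_max,v_min,min_area white-filter thresholds and min blob area.
#' @param search a [search_spec()].
#' @param filter_cutoff,filter_order zero-phase Butterworth settings.
#' @param min_prominence,min_separation_frac event-detector debouncing.
#' @param n_points samples per normalized gait cycle.
#' @param distortion a [distortion_coeffs()] or `NULL` for pass-through.
#' @param roi_margin px margin of the frame-to-frame subject-bounding-box
#'   search window.
#' @return a named list of class `trial_config`.
#' @export
trial_config <- function(h_tol_deg = 10, s_tol = 0.25, v_tol = 0.25,
                         s_max = 0.2, v_min = 0.8, min_area = 50,
                         search = search_spec(),
                         filter_cutoff = 10, filter_order = 4,
                         min_prominence = 10, min_separation_frac = 0.4,
                         n_points = 101, distortion = NULL,
                         roi_margin = 80) {
  structure(as.list(environment()), class = "trial_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields override [trial_config()] defaults; `search` may be a
#' mapping with [search_spec()] fields.
#'
#' @param path YAML file.
#' @return a `trial_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$search)) y$search <- do.call(search_spec, y$search)
  do.call(trial_config, y)
}

read_landmarks_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  l$static <- lapply(l$static, as.numeric)
  l$PL <- lapply(l$PL, as.numeric)
  l
}

#' Run the full markerless gait-analysis pipeline on a trial directory
#'
#' Expects the layout written by [simulate_trial()] (or equivalent real
#' data): `manifest.json`, `background.png`, `static.png`, a `frames/`
#' sequence and `landmarks.json`. Executes preprocessing, event detection,
#' model calibration, bottom-up tracking for every detected gait cycle,
#' kinematics filtering and time normalization, and (optionally) waveform
#' comparison against reference curves.
#'
#' @param trial_dir trial directory.
#' @param config a [trial_config()].
#' @param out_dir output directory (default `<trial_dir>/output`); set to
#'   `NULL` to skip writing files.
#' @param reference optional path to a reference-curves CSV (columns
#'   `percent`, `hip`, `knee`, `ankle`, `pelvic_tilt`) compared against
#'   the first-cycle estimated curves.
#' @return object of class `gait_result`: events, spatiotemporal
#'   parameters, per-frame angle estimates, per-cycle 101-point normalized
#'   curves, comparison metrics (when a reference is given), body model
#'   and run report.
#' @export
run_pipeline <- function(trial_dir, config = trial_config(),
                         out_dir = file.path(trial_dir, "output"),
                         reference = NULL) {
  man <- jsonlite::read_json(file.path(trial_dir, "manifest.json"),
                             simplifyVector = TRUE)
  lm_path <- file.path(trial_dir, "landmarks.json")
  if (!file.exists(lm_path))
    gait2d_stop("gait2d_missing_landmarks",
                paste("landmark file not found:", lm_path))
  landmarks <- read_landmarks_json(lm_path)
  fps <- man$fps
  report <- list(stages = list(), warnings = list(), config = unclass(config))

  bg <- background_model(read_frame_png(file.path(trial_dir, man$background)),
                         h_tol_deg = config$h_tol_deg, s_tol = config$s_tol,
                         v_tol = config$v_tol)

  # --- calibration (static image) ---
  static_rgb <- undistort_frame(read_frame_png(file.path(trial_dir, man$static)),
                                config$distortion)
  model <- calibrate_body(static_rgb, bg,
                          c(landmarks$static,
                            list(foot_length_mm = landmarks$foot_length_mm)),
                          thresholds = list(s_max = config$s_max,
                                            v_min = config$v_min,
                                            min_area = config$min_area))
  report$stages$calibration <- "ok"

  # --- per-frame preprocessing ---
  n <- man$n_frames
  features <- vector("list", n)
  fstate <- foot_tracker_state()
  roi <- NULL
  pelvis_cx <- foot_fg_cx <- foot_bg_cx <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rgb <- undistort_frame(read_frame_png(file.path(trial_dir, man$frames[i])),
                           config$distortion)
    ft <- tryCatch({
      sil <- segment_foreground(rgb, bg, roi = roi)
      blobs <- extract_garment_markers(rgb, sil, s_max = config$s_max,
                                       v_min = config$v_min,
                                       min_area = config$min_area)
      mk <- label_markers(blobs, fstate, frame = i)
      roi <- pmax(pmin(c(sil$bbox[1] - config$roi_margin,
                         sil$bbox[2] + config$roi_margin,
                         sil$bbox[3] - config$roi_margin,
                         sil$bbox[4] + config$roi_margin),
                       c(man$width, man$width, man$height, man$height)), 1)
      fstate <- update_foot_state(fstate, mk, i)
      list(sil_contour = sil$contour, markers = mk)
    }, gait2d_error = function(e) {
      report$warnings[[length(report$warnings) + 1]] <<-
        list(frame = i, message = conditionMessage(e))
      roi <<- NULL
      list(sil_contour = NULL, markers = NULL)
    })
    features[[i]] <- ft
    if (!is.null(ft$markers)) {
      pelvis_cx[i] <- ft$markers$pelvis$centroid[1]
      if (isTRUE(ft$markers$merged)) {
        # the individual foot centroids are unobservable while the socks
        # overlap; leave them missing and interpolate across the merge
        report$warnings[[length(report$warnings) + 1]] <-
          list(frame = i, message = "merged foot markers")
      } else {
        foot_fg_cx[i] <- ft$markers$foot_fg$centroid[1]
        foot_bg_cx[i] <- ft$markers$foot_bg$centroid[1]
      }
    }
  }
  report$stages$preprocessing <- "ok"

  fill <- function(x) {
    if (all(is.na(x))) gait2d_stop("gait2d_no_subject", "no frame was segmented")
    approx(seq_len(n), x, xout = seq_len(n), rule = 2)$y
  }
  pelvis_cx <- fill(pelvis_cx); foot_fg_cx <- fill(foot_fg_cx)

  # --- events & spatiotemporal parameters ---
  events <- detect_gait_events(pelvis_cx, foot_fg_cx, fps,
                               min_prominence = config$min_prominence,
                               min_separation_frac = config$min_separation_frac)
  params <- spatiotemporal_params(events, foot_fg_cx, model$mm_per_px, fps)
  report$stages$events <- "ok"

  # --- tracking per cycle ---
  cycles <- events$cycles
  poses <- list(); curves <- list()
  for (ci in seq_len(nrow(cycles))) {
    cy <- unname(cycles[ci, ])
    pl_first <- landmarks$PL[[as.character(cy[1])]]
    pl_last <- landmarks$PL[[as.character(cy[2])]]
    if (is.null(pl_first) || is.null(pl_last))
      gait2d_stop("gait2d_missing_landmarks",
                  "PL landmark missing for a cycle boundary frame")
    pp_of <- function(fr) {
      mk <- features[[fr]]$markers
      if (is.null(mk)) gait2d_stop("gait2d_missing_landmarks",
                                   "pelvis marker missing at a cycle boundary")
      most_posterior_point(marker_upper_contour(mk$pelvis))
    }
    pcal <- double_calibrate_pelvis(pl_first, pp_of(cy[1]),
                                    pl_last, pp_of(cy[2]), M = cy[2] - cy[1])
    to_in <- events$toe_offs[events$toe_offs > cy[1] & events$toe_offs < cy[2]]
    stance <- if (length(to_in)) cy[1]:to_in[1] else integer(0)
    pose <- track_cycle(features[cy[1]:cy[2]], model, pcal, stance, cy,
                        search = config$search)
    poses[[ci]] <- pose

    filt <- function(x) lowpass_filter(x, fps, config$filter_cutoff,
                                       config$filter_order)
    norm101 <- function(x) time_normalize(x, 1, length(x), config$n_points)
    curves[[ci]] <- data.frame(
      percent = seq(0, 100, length.out = config$n_points),
      hip = norm101(filt(pose$hip)), knee = norm101(filt(pose$knee)),
      ankle = norm101(filt(pose$ankle)),
      pelvic_tilt = norm101(filt(pose$pelvic_tilt)))
    gapped <- pose$frame[pose$flags == "gap_interpolated"]
    if (length(gapped))
      report$warnings[[length(report$warnings) + 1]] <-
        list(cycle = ci, message = paste("interpolated tracking gap at frames",
                                         paste(gapped, collapse = ", ")))
  }
  report$stages$tracking <- "ok"

  metrics <- NULL
  if (!is.null(reference)) {
    ref <- read.csv(reference)
    metrics <- lapply(c("hip", "knee", "ankle", "pelvic_tilt"), function(jn) {
      compare_curves(curves[[1]][[jn]], ref[[jn]])
    })
    names(metrics) <- c("hip", "knee", "ankle", "pelvic_tilt")
    report$stages$metrics <- "ok"
  }

  result <- structure(list(events = events, params = params,
                           cycles = cycles, poses = poses, curves = curves,
                           metrics = metrics, model = model,
                           report = report, fps = fps,
                           mm_per_px = model$mm_per_px),
                      class = "gait_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

#' @export
print.gait_result <- function(x, ...) {
  cat("<gait_result>\n")
  print(x$events)
  print(x$params)
  cat(sprintf("  scale: %.3f mm/px, %d cycle(s) tracked, %d warning(s)\n",
              x$mm_per_px, length(x$poses), length(x$report$warnings)))
  invisible(x)
}

# write the standard output files of a run
write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(result$poses))
    write.csv(do.call(rbind, result$poses),
              file.path(out_dir, "angles.csv"), row.names = FALSE)
  ev <- result$events
  evd <- rbind(
    data.frame(frame = ev$heel_strikes, type = "heel_strike"),
    data.frame(frame = ev$toe_offs, type = "toe_off"))
  evd <- evd[order(evd$frame), ]
  evd$time_s <- (evd$frame - 1) / result$fps
  evd$side <- ev$side
  write.csv(evd, file.path(out_dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(result$params[c("cadence", "walking_speed",
                                       "stride_time", "stride_length")],
                       file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ci in seq_along(result$curves))
    write.csv(result$curves[[ci]],
              file.path(out_dir, sprintf("curves_cycle%d.csv", ci)),
              row.names = FALSE)
  if (!is.null(result$metrics))
    jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
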