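# Configuration-driven end-to-end runner and named fixture presets.

#' Pipeline configuration
#'
#' Defaults mirror the analysis conventions used throughout the package:
#' 1 mm section offsets, 11 sections, a +/-20% isometric window and a
#' right elbow.
#'
#' @param input_dir directory holding per-frame meshes and sidecars.
#' @param frame_pattern regular expression matching per-frame mesh files
#'   (sorted lexicographically into frame order).
#' @param landmarks,aspects,ulna_planes sidecar file names inside
#'   `input_dir`.
#' @param offset_spacing section-plane spacing (mm).
#' @param offset_count number of section planes (odd, >= 3).
#' @param threshold_pct isometric window half-width (percent).
#' @param side `"right"` or `"left"` elbow.
#' @param lateral_origin see [normalize_intersection()].
#' @param trim_tol section-curve trim tolerance (relative).
#' @param seed RNG seed for any randomized stage.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir,
                            frame_pattern = "^frame_\\d+\\.ply$",
                            landmarks = "landmarks.csv",
                            aspects = "aspects.json",
                            ulna_planes = "ulna_planes.json",
                            offset_spacing = 1, offset_count = 11L,
                            threshold_pct = 20, side = "right",
                            lateral_origin = "lateral_center",
                            trim_tol = 0.25, seed = 1L,
                            output_dir = NULL) {
  cfg <- list(input_dir = input_dir, frame_pattern = frame_pattern,
              landmarks = landmarks, aspects = aspects,
              ulna_planes = ulna_planes, offset_spacing = offset_spacing,
              offset_count = as.integer(offset_count),
              threshold_pct = threshold_pct, side = side,
              lateral_origin = lateral_origin, trim_tol = trim_tol,
              seed = as.integer(seed), output_dir = output_dir)
  if (cfg$offset_count < 3L || cfg$offset_count %% 2L == 0L) {
    stop("offset_count must be an odd integer >= 3", call. = FALSE)
  }
  if (cfg$threshold_pct <= 0) stop("threshold_pct must be > 0",
                                   call. = FALSE)
  if (cfg$offset_spacing <= 0) stop("offset_spacing must be > 0",
                                    call. = FALSE)
  if (!cfg$side %in% c("right", "left")) {
    stop("side must be 'right' or 'left'", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file with [pipeline_config()]
#'   fields.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

#' Generate a named synthetic fixture
#'
#' Presets:
#' \describe{
#'   \item{fixed_axis}{the rotation axis is the transcondylar line in every
#'     frame (no drift); the ideal hinge.}
#'   \item{drifting_axis}{the horizontal axis angle sweeps from 0 to about
#'     47 degrees across flexion and the axis point migrates superiorly, so
#'     the medial intersections travel anterior-inferior to
#'     posterior-superior and the lateral ones posterior-inferior to
#'     anterior-superior; only the low-flexion frames stay inside the
#'     +/-20% window.}
#'   \item{noisy}{fixed axis plus seeded Gaussian vertex noise
#'     (`noise_sigma`).}
#' }
#'
#' @param preset one of `"fixed_axis"`, `"drifting_axis"`, `"noisy"`.
#' @param out_dir output directory.
#' @param seed RNG seed (only the noisy preset consumes randomness).
#' @param n_frames frames across the flexion range.
#' @param max_flexion_deg flexion range of motion (deg).
#' @param params [elbow_params()].
#' @param noise_sigma vertex noise SD (mm) for the noisy preset.
#' @return `out_dir`, invisibly.
#' @export
make_fixture <- function(preset, out_dir, seed = 1L, n_frames = 30L,
                         max_flexion_deg = 106.5, params = elbow_params(),
                         noise_sigma = 0.2) {
  presets <- c("fixed_axis", "drifting_axis", "noisy")
  if (!preset %in% presets) {
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  angles <- seq(0, max_flexion_deg, length.out = n_frames)
  traj <- switch(preset,
    fixed_axis = ,
    noisy = axis_trajectory(flexion_angles = angles),
    drifting_axis = axis_trajectory(
      flexion_angles = angles,
      horizontal_drift = function(a) -47 * (a / max_flexion_deg)^3,
      axis_point_offset = function(a) c(0, 5.7 * a / max_flexion_deg, 0)))
  hum <- make_distal_humerus(params)
  uln <- make_proximal_ulna(params)
  posed <- pose_sequence(uln, traj, hum$truth)
  if (preset == "noisy") {
    posed$meshes <- lapply(seq_along(posed$meshes), function(k) {
      add_vertex_noise(posed$meshes[[k]], noise_sigma, seed + k)
    })
  }
  write_fixture(out_dir, posed, hum)
  invisible(out_dir)
}

read_pipeline_inputs <- function(cfg) {
  files <- sort(list.files(cfg$input_dir, pattern = cfg$frame_pattern,
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no frame meshes matching '", cfg$frame_pattern, "' in ",
         cfg$input_dir, call. = FALSE)
  }
  reader <- function(f) {
    if (grepl("\\.stl$", f, ignore.case = TRUE)) read_stl(f) else read_ply(f)
  }
  meshes <- lapply(files, reader)
  lm_df <- utils::read.csv(file.path(cfg$input_dir, cfg$landmarks))
  landmarks <- lapply(seq_along(meshes), function(k) {
    sub <- lm_df[lm_df$frame == k, ]
    if (nrow(sub) != 3L) stop("frame ", k, ": expected 3 landmarks",
                              call. = FALSE)
    as.matrix(sub[order(sub$landmark_id), c("x", "y", "z")])
  })
  aspects <- jsonlite::read_json(file.path(cfg$input_dir, cfg$aspects),
                                 simplifyVector = TRUE)
  planes_path <- file.path(cfg$input_dir, cfg$ulna_planes)
  ulna_planes <- NULL
  if (file.exists(planes_path)) {
    raw <- jsonlite::read_json(planes_path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    ulna_planes <- lapply(raw, function(p) plane3(unlist(p$point),
                                                  unlist(p$normal)))
  }
  hmesh <- NULL
  if (!is.null(aspects$humerus_mesh)) {
    hp <- file.path(cfg$input_dir, aspects$humerus_mesh)
    if (file.exists(hp)) hmesh <- reader(hp)
  }
  list(meshes = meshes, landmarks = landmarks, aspects = aspects,
       ulna_planes = ulna_planes, humerus_mesh = hmesh)
}

#' Run the full analysis pipeline
#'
#' Reads the posed meshes and sidecars, builds the humerus frame from the
#' aspect rims, estimates the per-frame rotation axis from the notch,
#' computes flexion angles, aspect intersections, normalized coordinates,
#' quadrants, axis angles, the isometric window and the trend tests.
#'
#' @param config `pipeline_config`, a list of its fields, or a path to a
#'   YAML/JSON config file.
#' @return result bundle: `frame`, `medial`/`lateral` aspect circles,
#'   per-frame table `frames` (data.frame), `intersections`, `angles`
#'   data.frames, `window`, `trends`, `angle_summary`, `failures`,
#'   `exit_status` (0 ok, 1 partial: > 20% of frames failed, 2 fatal).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) {
    config
  } else if (is.character(config)) {
    read_pipeline_config(config)
  } else {
    do.call(pipeline_config, config)
  }
  inp <- read_pipeline_inputs(cfg)
  medial <- fit_aspect_circle(as_points(inp$aspects$medial$rim_points),
                              side = "medial")
  lateral <- fit_aspect_circle(as_points(inp$aspects$lateral$rim_points),
                               side = "lateral")
  frame <- build_frame(medial, lateral,
                       shaft_dir = unlist(inp$aspects$shaft_dir),
                       posterior_hint = unlist(inp$aspects$posterior_hint),
                       humerus_mesh = inp$humerus_mesh,
                       side = if (is.null(inp$aspects$side)) cfg$side else
                         inp$aspects$side)
  humeral_plane <- plane3(frame$origin, frame$Z)
  axis_cfg <- list(offset_spacing = cfg$offset_spacing,
                   offset_count = cfg$offset_count,
                   trim_tol = cfg$trim_tol, lateral_dir = frame$X)
  n <- length(inp$meshes)
  axes <- vector("list", n)
  failures <- list()
  frame_rows <- list()
  inter_rows <- list()
  angle_rows <- list()
  for (k in seq_len(n)) {
    res <- tryCatch({
      ax <- estimate_instantaneous_axis(inp$meshes[[k]], inp$landmarks[[k]],
                                        axis_cfg)
      ax$frame_index <- k
      flex <- if (!is.null(inp$ulna_planes)) {
        flexion_angle(inp$ulna_planes[[k]], humeral_plane,
                      axis_x = frame$X, frame_index = k)$angle
      } else {
        NA_real_
      }
      ang <- axis_angles(ax, frame, frame_index = k)
      rows <- lapply(list(medial, lateral), function(asp) {
        p <- intersect_axis_with_aspect(ax, asp)
        yz <- normalize_intersection(p, frame, asp,
                                     lateral_origin = cfg$lateral_origin)
        quad <- classify_quadrant(yz[["y_pct"]], yz[["z_pct"]])
        data.frame(frame = k, flexion_deg = flex, side = asp$side,
                   x = p[1L], y = p[2L], z = p[3L],
                   y_pct = yz[["y_pct"]], z_pct = yz[["z_pct"]],
                   quadrant = as.character(quad),
                   tie = isTRUE(attr(quad, "tie")))
      })
      list(ax = ax, flex = flex, ang = ang, rows = rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(frame = k,
                                                message = conditionMessage(res))
      next
    }
    axes[[k]] <- res$ax
    frame_rows[[k]] <- data.frame(
      frame = k, flexion_deg = res$flex,
      px = res$ax$point[1L], py = res$ax$point[2L], pz = res$ax$point[3L],
      dx = res$ax$direction[1L], dy = res$ax$direction[2L],
      dz = res$ax$direction[3L], rms_residual = res$ax$rms_residual)
    inter_rows[[k]] <- do.call(rbind, res$rows)
    angle_rows[[k]] <- data.frame(frame = k, flexion_deg = res$flex,
                                  coronal_deg = res$ang$coronal_deg,
                                  horizontal_deg = res$ang$horizontal_deg,
                                  coronal_signed_deg = res$ang$coronal_signed_deg,
                                  horizontal_signed_deg = res$ang$horizontal_signed_deg)
  }
  fail_frac <- length(failures) / n
  if (fail_frac == 1) {
    stop("all frames failed; first error: ", failures[[1L]]$message,
         call. = FALSE)
  }
  frames_df <- do.call(rbind, frame_rows)
  inter_df <- do.call(rbind, inter_rows)
  angles_df <- do.call(rbind, angle_rows)
  window <- isometric_window(inter_df, threshold_pct = cfg$threshold_pct)
  trends <- list()
  if (!all(is.na(inter_df$flexion_deg))) {
    med <- inter_df[inter_df$side == "medial", ]
    lat <- inter_df[inter_df$side == "lateral", ]
    trends <- list(
      medial_z_vs_flexion = linear_trend(med$flexion_deg, med$z_pct),
      medial_y_vs_z = linear_trend(med$z_pct, med$y_pct),
      lateral_z_vs_flexion = linear_trend(lat$flexion_deg, lat$z_pct),
      lateral_y_vs_z = linear_trend(lat$z_pct, lat$y_pct))
  }
  summaries <- list(coronal = angle_summary(angles_df$coronal_deg),
                    horizontal = angle_summary(angles_df$horizontal_deg))
  bundle <- list(config = cfg, frame = frame, medial = medial,
                 lateral = lateral, axes = axes, frames = frames_df,
                 intersections = inter_df, angles = angles_df,
                 window = window, trends = trends,
                 angle_summary = summaries, failures = failures,
                 exit_status = if (fail_frac > 0.2) 1L else 0L)
  class(bundle) <- "pipeline_result"
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(bundle, cfg$output_dir)
  bundle
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("elbow axis pipeline:", nrow(x$frames), "frames analyzed,",
      length(x$failures), "failed\n")
  cat(sprintf("  coronal angle  %.1f (SD %.1f) deg\n",
              x$angle_summary$coronal[["mean"]],
              x$angle_summary$coronal[["sd"]]))
  cat(sprintf("  horizontal angle %.1f (SD %.1f) deg\n",
              x$angle_summary$horizontal[["mean"]],
              x$angle_summary$horizontal[["sd"]]))
  cat("  isometric window frames:",
      paste(x$window$selected_frames, collapse = " "), "\n")
  invisible(x)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(bundle$frames, file.path(out_dir, "axes.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$intersections,
                   file.path(out_dir, "intersections.csv"), row.names = FALSE)
  utils::write.csv(bundle$angles, file.path(out_dir, "angles.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$window, file.path(out_dir, "window.json"),
                       auto_unbox = TRUE, digits = NA)
  summary <- list(
    trends = lapply(bundle$trends, function(tr) {
      list(slope = tr$slope, t = tr$t_statistic, p = tr$p_value, n = tr$n)
    }),
    angle_summary = lapply(bundle$angle_summary, as.list),
    failures = bundle$failures,
    exit_status = bundle$exit_status)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
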