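# Parametric synthetic elbow with known ground-truth kinematics.
#
# The distal humerus is a stylized frustum whose medial and lateral faces are
# planar disks (the "aspects"); the proximal ulna is a curved shell whose
# concave inner surface is an exact cylinder arc standing in for the greater
# sigmoid notch. Posing rotates the ulna about a prescribed, possibly
# drifting, axis so every estimator stage can be tested by parameter
# recovery.
#
# Humerus-fixed world coordinates: X mediolateral (medial aspect center at
# the origin, +X toward lateral), Y along the humeral shaft (+Y superior),
# +Z posterior. All lengths mm, all angles degrees.

#' Parameters of the synthetic elbow
#'
#' Defaults are anatomically plausible adult dimensions; none are fitted to
#' any particular specimen.
#'
#' @param notch_radius radius (mm) of the greater sigmoid notch cylinder.
#' @param notch_width mediolateral extent (mm) of the notch.
#' @param notch_arc angular extent (deg) of the concave arc, in (0, 360).
#' @param medial_aspect_radius radius (mm) of the medial aspect disk.
#' @param lateral_aspect_radius radius (mm) of the lateral aspect disk.
#' @param transcondylar_length distance (mm) between the aspect centers.
#' @param mesh_resolution target vertex spacing (mm); must be below
#'   `notch_radius / 4`.
#' @param shell_thickness radial thickness (mm) of the ulna shell.
#' @return object of class `elbow_params`.
#' @export
elbow_params <- function(notch_radius = 12, notch_width = 18,
                         notch_arc = 170, medial_aspect_radius = 10,
                         lateral_aspect_radius = 8,
                         transcondylar_length = 50,
                         mesh_resolution = 0.75, shell_thickness = 6) {
  p <- list(notch_radius = notch_radius, notch_width = notch_width,
            notch_arc = notch_arc,
            medial_aspect_radius = medial_aspect_radius,
            lateral_aspect_radius = lateral_aspect_radius,
            transcondylar_length = transcondylar_length,
            mesh_resolution = mesh_resolution,
            shell_thickness = shell_thickness)
  lens <- c(p$notch_radius, p$notch_width, p$medial_aspect_radius,
            p$lateral_aspect_radius, p$transcondylar_length,
            p$mesh_resolution, p$shell_thickness)
  if (any(!is.finite(unlist(p))) || any(lens <= 0)) {
    stop("all lengths must be positive and finite", call. = FALSE)
  }
  if (p$notch_arc <= 0 || p$notch_arc >= 360) {
    stop("notch_arc must lie strictly between 0 and 360 degrees",
         call. = FALSE)
  }
  if (p$mesh_resolution >= p$notch_radius / 4) {
    stop("mesh_resolution must be finer than notch_radius / 4", call. = FALSE)
  }
  structure(p, class = "elbow_params")
}

#' Prescribed rotation-axis trajectory across flexion
#'
#' The axis direction at flexion angle `a` is
#' `unit(c(1, tan(coronal_drift(a)), tan(horizontal_drift(a))))` in humerus
#' coordinates (so both drift angles are the signed angles between the axis
#' and the transcondylar X axis after projection into the coronal XY and
#' horizontal XZ planes), and the axis passes through the transcondylar
#' midpoint displaced by `axis_point_offset(a)`.
#'
#' @param flexion_angles strictly increasing flexion angles (deg).
#' @param coronal_drift function mapping flexion angle to coronal tilt (deg).
#' @param horizontal_drift function mapping flexion angle to horizontal
#'   tilt (deg).
#' @param axis_point_offset function mapping flexion angle to a 3-vector
#'   offset (mm) of the axis point.
#' @return object of class `axis_trajectory`.
#' @export
axis_trajectory <- function(flexion_angles = seq(0, 106.5, length.out = 30),
                            coronal_drift = function(a) 0 * a,
                            horizontal_drift = function(a) 0 * a,
                            axis_point_offset = function(a) c(0, 0, 0)) {
  stopifnot(is.numeric(flexion_angles), length(flexion_angles) >= 1L)
  if (any(diff(flexion_angles) <= 0)) {
    stop("flexion_angles must be strictly increasing", call. = FALSE)
  }
  drifts_c <- vapply(flexion_angles, coronal_drift, numeric(1L))
  drifts_h <- vapply(flexion_angles, horizontal_drift, numeric(1L))
  if (any(!is.finite(drifts_c)) || any(!is.finite(drifts_h)) ||
      any(abs(c(drifts_c, drifts_h)) >= 90)) {
    stop("drift angles must be finite and within (-90, 90) degrees over the ",
         "full flexion range", call. = FALSE)
  }
  structure(list(flexion_angles = as.numeric(flexion_angles),
                 coronal_drift = coronal_drift,
                 horizontal_drift = horizontal_drift,
                 axis_point_offset = axis_point_offset),
            class = "axis_trajectory")
}

# Axis direction in humerus coordinates for given drift angles (deg).
axis_direction_from_drift <- function(coronal_deg, horizontal_deg) {
  unitv(c(1, tan(deg2rad(coronal_deg)), tan(deg2rad(horizontal_deg))))
}

# Rectangular grid patch: vertices fn(u, v) over the grid uu x vv, two
# triangles per cell. `flip` reverses orientation.
grid_patch <- function(uu, vv, fn, flip = FALSE) {
  nu <- length(uu); nv <- length(vv)
  verts <- matrix(0, nu * nv, 3L)
  k <- 1L
  for (i in seq_len(nu)) {
    for (j in seq_len(nv)) {
      verts[k, ] <- fn(uu[i], vv[j])
      k <- k + 1L
    }
  }
  idx <- function(i, j) (i - 1L) * nv + j
  faces <- matrix(0L, 2L * (nu - 1L) * (nv - 1L), 3L)
  k <- 1L
  for (i in seq_len(nu - 1L)) {
    for (j in seq_len(nv - 1L)) {
      p11 <- idx(i, j); p21 <- idx(i + 1L, j)
      p22 <- idx(i + 1L, j + 1L); p12 <- idx(i, j + 1L)
      faces[k, ] <- c(p11, p21, p22)
      faces[k + 1L, ] <- c(p11, p22, p12)
      k <- k + 2L
    }
  }
  if (flip) faces <- faces[, c(1L, 3L, 2L)]
  list(vertices = verts, faces = faces)
}

combine_patches <- function(patches) {
  offs <- 0L
  verts <- NULL; faces <- NULL
  for (p in patches) {
    verts <- rbind(verts, p$vertices)
    faces <- rbind(faces, p$faces + offs)
    offs <- offs + nrow(p$vertices)
  }
  merge_duplicate_vertices(verts, faces)
}

#' Generate the stylized distal humerus
#'
#' A frustum along the transcondylar X axis whose end faces are the planar
#' medial (at the origin) and lateral aspect disks.
#'
#' @param params [elbow_params()].
#' @return list with `mesh` (`trimesh`) and `truth`: exact aspect circles
#'   (center, radius, normal), `shaft_dir`, `posterior_dir` and the
#'   transcondylar length.
#' @export
make_distal_humerus <- function(params) {
  stopifnot(inherits(params, "elbow_params"))
  rm_ <- params$medial_aspect_radius
  rl <- params$lateral_aspect_radius
  tl <- params$transcondylar_length
  res <- params$mesh_resolution
  if (res > min(rm_, rl) / 2) {
    stop("mesh_resolution too coarse to represent the aspect disks",
         call. = FALSE)
  }
  ntheta <- max(16L, ceiling(2 * pi * max(rm_, rl) / res))
  nx <- max(2L, ceiling(tl / res) + 1L)
  xs <- seq(0, tl, length.out = nx)
  radii <- rm_ + (rl - rm_) * xs / tl
  thetas <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  ring <- function(i) cbind(xs[i], radii[i] * cos(thetas),
                            radii[i] * sin(thetas))
  verts <- do.call(rbind, lapply(seq_len(nx), ring))
  verts <- rbind(verts, c(0, 0, 0), c(tl, 0, 0))
  c0 <- nx * ntheta + 1L; c1 <- nx * ntheta + 2L
  rid <- function(i, j) (i - 1L) * ntheta + (j - 1L) %% ntheta + 1L
  faces <- list()
  for (i in seq_len(nx - 1L)) {
    for (j in seq_len(ntheta)) {
      a <- rid(i, j); b <- rid(i, j + 1L)
      c_ <- rid(i + 1L, j + 1L); d <- rid(i + 1L, j)
      faces[[length(faces) + 1L]] <- rbind(c(a, b, c_), c(a, c_, d))
    }
  }
  for (j in seq_len(ntheta)) {
    faces[[length(faces) + 1L]] <- rbind(
      c(c0, rid(1L, j + 1L), rid(1L, j)),
      c(c1, rid(nx, j), rid(nx, j + 1L)))
  }
  mesh <- trimesh(verts, do.call(rbind, faces))
  truth <- list(
    medial_aspect = list(center = c(0, 0, 0), radius = rm_,
                         normal = c(1, 0, 0)),
    lateral_aspect = list(center = c(tl, 0, 0), radius = rl,
                          normal = c(1, 0, 0)),
    shaft_dir = c(0, 1, 0), posterior_dir = c(0, 0, 1),
    transcondylar_length = tl)
  list(mesh = mesh, truth = truth)
}

#' Generate the stylized proximal ulna
#'
#' A curved shell whose concave inner surface is an exact cylinder arc of
#' radius `notch_radius` about the notch axis (the transcondylar midline),
#' opening toward the distal (-Y) direction. Three registration landmarks are
#' returned on the mid-width cross-section of the notch (the "highest
#' depression"), non-collinear.
#'
#' @param params [elbow_params()].
#' @return list with `mesh`, `notch_axis` (point + dir), `landmarks`
#'   (3 x 3 matrix, rows are points on the notch surface) and
#'   `coronal_plane` (`plane3` attached to the ulna at the reference pose).
#' @export
make_proximal_ulna <- function(params) {
  stopifnot(inherits(params, "elbow_params"))
  r <- params$notch_radius
  th <- params$shell_thickness
  w <- params$notch_width
  arc <- params$notch_arc
  res <- params$mesh_resolution
  q0 <- c(params$transcondylar_length / 2, 0, 0)
  # beta measured in the YZ plane; beta = 180 deg points distal (-Y),
  # the deepest point of the notch.
  b1 <- deg2rad(180 - arc / 2)
  b2 <- deg2rad(180 + arc / 2)
  nb <- max(9L, ceiling((b2 - b1) * (r + th) / res) + 1L)
  nxg <- max(3L, ceiling(w / res) + 1L)
  if (nxg %% 2L == 0L) nxg <- nxg + 1L
  nr <- max(2L, ceiling(th / res) + 1L)
  xs <- seq(-w / 2, w / 2, length.out = nxg)
  betas <- seq(b1, b2, length.out = nb)
  rhos <- seq(r, r + th, length.out = nr)
  fn <- function(x, beta, rho) {
    q0 + c(x, rho * cos(beta), rho * sin(beta))
  }
  patches <- list(
    grid_patch(xs, betas, function(x, b) fn(x, b, r), flip = FALSE),
    grid_patch(xs, betas, function(x, b) fn(x, b, r + th), flip = TRUE),
    grid_patch(betas, rhos, function(b, rho) fn(xs[nxg], b, rho),
               flip = TRUE),
    grid_patch(betas, rhos, function(b, rho) fn(xs[1L], b, rho),
               flip = FALSE),
    grid_patch(xs, rhos, function(x, rho) fn(x, betas[1L], rho),
               flip = TRUE),
    grid_patch(xs, rhos, function(x, rho) fn(x, betas[nb], rho),
               flip = FALSE))
  mesh <- combine_patches(patches)
  delta <- deg2rad(min(40, 0.4 * arc))
  bc <- pi
  landmarks <- rbind(fn(0, bc - delta, r), fn(0, bc, r), fn(0, bc + delta, r))
  list(mesh = mesh,
       notch_axis = list(point = q0, dir = c(1, 0, 0)),
       landmarks = landmarks,
       coronal_plane = plane3(q0, c(0, 0, 1)))
}

#' Pose an ulna across a flexion sequence
#'
#' At each flexion angle the reference ulna is carried rigidly onto the
#' frame's prescribed rotation axis (so the notch cylinder axis coincides
#' with it) and rotated about that axis by the flexion angle. The stored
#' ground truth is therefore exactly the axis the notch-based estimator
#' should recover in every frame.
#'
#' @param ulna output of [make_proximal_ulna()].
#' @param traj [axis_trajectory()].
#' @param humerus_truth `truth` element of [make_distal_humerus()].
#' @return list with `meshes` (list of `trimesh`), `landmarks` (list of
#'   3 x 3 matrices), `transforms` (list of `rigid_transform`),
#'   `ulna_planes` (per-frame `plane3`) and `truth` (`ground_truth`).
#' @export
pose_sequence <- function(ulna, traj, humerus_truth) {
  stopifnot(inherits(traj, "axis_trajectory"))
  if (is.null(ulna$notch_axis)) {
    stop("ulna must carry its notch_axis (use make_proximal_ulna)",
         call. = FALSE)
  }
  q0 <- ulna$notch_axis$point
  x_dir <- ulna$notch_axis$dir
  angles <- traj$flexion_angles
  meshes <- vector("list", length(angles))
  lms <- vector("list", length(angles))
  tfs <- vector("list", length(angles))
  planes <- vector("list", length(angles))
  frames <- vector("list", length(angles))
  for (k in seq_along(angles)) {
    a <- angles[k]
    d <- axis_direction_from_drift(traj$coronal_drift(a),
                                   traj$horizontal_drift(a))
    p <- q0 + as.numeric(traj$axis_point_offset(a))
    Ra <- rot_between(x_dir, d)
    align <- rigid_transform(Ra, p - as.numeric(Ra %*% q0))
    flex <- rigid_about_axis(p, d, a)
    tf <- compose_rigid(flex, align)
    meshes[[k]] <- transform_mesh(ulna$mesh, tf)
    lms[[k]] <- apply_rigid(tf, ulna$landmarks)
    tfs[[k]] <- tf
    planes[[k]] <- plane3(apply_rigid(tf, ulna$coronal_plane$point),
                          as.numeric(tf$R %*% ulna$coronal_plane$normal))
    frames[[k]] <- list(flexion_deg = a, axis_point = p, axis_dir = d)
  }
  truth <- ground_truth(frames = frames,
                        medial_aspect = humerus_truth$medial_aspect,
                        lateral_aspect = humerus_truth$lateral_aspect,
                        shaft_dir = humerus_truth$shaft_dir,
                        posterior_dir = humerus_truth$posterior_dir)
  list(meshes = meshes, landmarks = lms, transforms = tfs,
       ulna_planes = planes, truth = truth)
}

#' Ground-truth record of a synthetic sequence
#'
#' @param frames list of per-frame records `(flexion_deg, axis_point,
#'   axis_dir)`.
#' @param medial_aspect,lateral_aspect exact aspect circles.
#' @param shaft_dir,posterior_dir unit direction of the humeral shaft
#'   (superior) and the posterior direction.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(frames, medial_aspect, lateral_aspect, shaft_dir,
                         posterior_dir = c(0, 0, 1)) {
  for (fr in frames) {
    if (abs(vnorm(fr$axis_dir) - 1) > 1e-9) {
      stop("ground-truth axis directions must be unit-norm", call. = FALSE)
    }
  }
  structure(list(frames = frames, medial_aspect = medial_aspect,
                 lateral_aspect = lateral_aspect,
                 shaft_dir = unitv(shaft_dir),
                 posterior_dir = unitv(posterior_dir)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  a <- vapply(x$frames, `[[`, numeric(1L), "flexion_deg")
  cat("ground truth:", length(x$frames), "frames, flexion",
      sprintf("%.1f..%.1f deg\n", min(a), max(a)))
  invisible(x)
}

#' Add i.i.d. Gaussian noise to mesh vertices
#'
#' @param mesh `trimesh`.
#' @param sigma per-coordinate standard deviation (mm); 0 returns the mesh
#'   unchanged.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return noisy `trimesh`.
#' @export
add_vertex_noise <- function(mesh, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(mesh)
  n <- nrow(mesh$vertices)
  noise <- with_seed(seed, matrix(stats::rnorm(3L * n, sd = sigma), n, 3L))
  trimesh(mesh$vertices + noise, mesh$faces)
}

# Points on an aspect rim circle, optionally jittered (seeded).
aspect_rim_points <- function(aspect, n = 24L, jitter_sd = 0, seed = 1L) {
  pl <- plane3(aspect$center, aspect$normal)
  b <- plane_basis(pl)
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- t(vapply(t, function(tt) {
    aspect$center + aspect$radius * (cos(tt) * b$e1 + sin(tt) * b$e2)
  }, numeric(3L)))
  if (jitter_sd > 0) {
    pts <- pts + with_seed(seed, matrix(stats::rnorm(3L * n, sd = jitter_sd),
                                        n, 3L))
  }
  pts
}

#' Write a synthetic fixture to disk
#'
#' Emits per-frame PLY meshes, the humerus mesh, a landmarks CSV
#' (`frame,landmark_id,x,y,z`), an aspects/shaft sidecar JSON, per-frame
#' ulna coronal planes JSON and the ground-truth JSON. Round-trips through
#' [read_fixture()] at float32 precision.
#'
#' @param dir_path output directory (created if needed).
#' @param posed output of [pose_sequence()].
#' @param humerus output of [make_distal_humerus()].
#' @param rim_n rim points sampled per aspect for the sidecar.
#' @param rim_jitter_sd,seed optional rim-point jitter (mm) and its seed.
#' @param mesh_format passed to [write_ply()].
#' @return `dir_path`, invisibly.
#' @export
write_fixture <- function(dir_path, posed, humerus, rim_n = 24L,
                          rim_jitter_sd = 0, seed = 1L,
                          mesh_format = "binary_little_endian") {
  if (length(posed$meshes) == 0L) {
    stop("fixture must contain at least one frame", call. = FALSE)
  }
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir_path, call. = FALSE)
  }
  truth <- posed$truth
  for (k in seq_along(posed$meshes)) {
    write_ply(posed$meshes[[k]],
              file.path(dir_path, sprintf("frame_%03d.ply", k)),
              format = mesh_format)
  }
  write_ply(humerus$mesh, file.path(dir_path, "humerus.ply"),
            format = mesh_format)
  lm_df <- do.call(rbind, lapply(seq_along(posed$landmarks), function(k) {
    m <- posed$landmarks[[k]]
    data.frame(frame = k, landmark_id = seq_len(nrow(m)),
               x = m[, 1L], y = m[, 2L], z = m[, 3L])
  }))
  utils::write.csv(lm_df, file.path(dir_path, "landmarks.csv"),
                   row.names = FALSE)
  aspects <- list(
    medial = list(rim_points = aspect_rim_points(truth$medial_aspect, rim_n,
                                                 rim_jitter_sd, seed),
                  radius = truth$medial_aspect$radius),
    lateral = list(rim_points = aspect_rim_points(truth$lateral_aspect, rim_n,
                                                  rim_jitter_sd, seed + 1L),
                   radius = truth$lateral_aspect$radius),
    shaft_dir = truth$shaft_dir,
    posterior_hint = truth$posterior_dir,
    side = "right",
    humerus_mesh = "humerus.ply")
  jsonlite::write_json(aspects, file.path(dir_path, "aspects.json"),
                       auto_unbox = TRUE, digits = NA)
  planes <- lapply(seq_along(posed$ulna_planes), function(k) {
    pl <- posed$ulna_planes[[k]]
    list(frame = k, point = pl$point, normal = pl$normal)
  })
  jsonlite::write_json(planes, file.path(dir_path, "ulna_planes.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- list(frames = lapply(seq_along(truth$frames), function(k) {
    fr <- truth$frames[[k]]
    list(frame = k, flexion_deg = fr$flexion_deg,
         axis_point = fr$axis_point, axis_dir = fr$axis_dir)
  }),
  medial_aspect = truth$medial_aspect,
  lateral_aspect = truth$lateral_aspect,
  shaft_dir = truth$shaft_dir, posterior_dir = truth$posterior_dir)
  jsonlite::write_json(tr, file.path(dir_path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir_path)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir_path fixture directory.
#' @return list with `meshes`, `humerus_mesh`, `landmarks` (per-frame
#'   matrices), `aspects`, `ulna_planes` and `truth` (`ground_truth`).
#' @export
read_fixture <- function(dir_path) {
  frame_files <- sort(list.files(dir_path, pattern = "^frame_\\d+\\.ply$",
                                 full.names = TRUE))
  if (length(frame_files) == 0L) {
    stop("no frame_*.ply meshes found in ", dir_path, call. = FALSE)
  }
  meshes <- lapply(frame_files, read_ply)
  lm_df <- utils::read.csv(file.path(dir_path, "landmarks.csv"))
  landmarks <- lapply(sort(unique(lm_df$frame)), function(k) {
    sub <- lm_df[lm_df$frame == k, ]
    as.matrix(sub[order(sub$landmark_id), c("x", "y", "z")])
  })
  aspects <- jsonlite::read_json(file.path(dir_path, "aspects.json"),
                                 simplifyVector = TRUE)
  planes_raw <- jsonlite::read_json(file.path(dir_path, "ulna_planes.json"),
                                    simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ulna_planes <- lapply(planes_raw, function(p) {
    plane3(unlist(p$point), unlist(p$normal))
  })
  tr_raw <- jsonlite::read_json(file.path(dir_path, "truth.json"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  frames <- lapply(tr_raw$frames, function(fr) {
    list(flexion_deg = fr$flexion_deg,
         axis_point = unlist(fr$axis_point),
         axis_dir = unitv(unlist(fr$axis_dir)))
  })
  truth <- ground_truth(frames = frames,
                        medial_aspect = lapply(tr_raw$medial_aspect, unlist),
                        lateral_aspect = lapply(tr_raw$lateral_aspect, unlist),
                        shaft_dir = unlist(tr_raw$shaft_dir),
                        posterior_dir = unlist(tr_raw$posterior_dir))
  hum_path <- file.path(dir_path, "humerus.ply")
  humerus_mesh <- if (file.exists(hum_path)) read_ply(hum_path) else NULL
  list(meshes = meshes, humerus_mesh = humerus_mesh, landmarks = landmarks,
       aspects = aspects, ulna_planes = ulna_planes, truth = truth)
}

#' Voxelize the synthetic bones analytically
#'
#' Rasterizes the exact solid geometry of the synthetic humerus or reference
#' ulna onto a regular grid (1 inside, 0 outside), for testing the
#' segmentation module against a known surface.
#'
#' @param params [elbow_params()].
#' @param spacing isotropic voxel size (mm).
#' @param bone `"humerus"` or `"ulna"`.
#' @param pad empty border voxels around the solid.
#' @return [image_volume()] with 0/1 intensities.
#' @export
voxelize_elbow <- function(params, spacing = 0.5,
                           bone = c("humerus", "ulna"), pad = 2L) {
  bone <- match.arg(bone)
  stopifnot(inherits(params, "elbow_params"), spacing > 0)
  tl <- params$transcondylar_length
  if (bone == "humerus") {
    rmax <- max(params$medial_aspect_radius, params$lateral_aspect_radius)
    lo <- c(0, -rmax, -rmax); hi <- c(tl, rmax, rmax)
  } else {
    r2 <- params$notch_radius + params$shell_thickness
    lo <- c(tl / 2 - params$notch_width / 2, -r2, -r2)
    hi <- c(tl / 2 + params$notch_width / 2, r2, r2)
  }
  lo <- lo - pad * spacing; hi <- hi + pad * spacing
  dims <- ceiling((hi - lo) / spacing) + 1L
  xs <- lo[1L] + (seq_len(dims[1L]) - 1L) * spacing
  ys <- lo[2L] + (seq_len(dims[2L]) - 1L) * spacing
  zs <- lo[3L] + (seq_len(dims[3L]) - 1L) * spacing
  arr <- array(0, dim = dims)
  if (bone == "humerus") {
    rad <- params$medial_aspect_radius +
      (params$lateral_aspect_radius - params$medial_aspect_radius) *
      pmin(1, pmax(0, xs / tl))
    inx <- xs >= 0 & xs <= tl
    yz2 <- outer(ys^2, zs^2, "+")
    for (i in which(inx)) arr[i, , ] <- (yz2 <= rad[i]^2) * 1
  } else {
    q0x <- tl / 2
    hw <- params$notch_width / 2
    r <- params$notch_radius; r2 <- r + params$shell_thickness
    b1 <- deg2rad(180 - params$notch_arc / 2)
    b2 <- deg2rad(180 + params$notch_arc / 2)
    inx <- abs(xs - q0x) <= hw
    rho <- sqrt(outer(ys^2, zs^2, "+"))
    beta <- atan2(outer(rep(1, length(ys)), zs),
                  outer(ys, rep(1, length(zs))))
    beta <- ifelse(beta < 0, beta + 2 * pi, beta)
    slab <- (rho >= r & rho <= r2 & beta >= b1 & beta <= b2) * 1
    for (i in which(inx)) arr[i, , ] <- slab
  }
  image_volume(arr, spacing = rep(spacing, 3L), origin = lo)
}
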