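# Shared synthetic fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- force(expr)
  .fx_cache[[key]]
}

# Coarser mesh for unit tests (still well under notch_radius / 4).
small_params <- function() elbow_params(mesh_resolution = 1.2)

small_ulna <- function() fx_memo("ulna_s", make_proximal_ulna(small_params()))
small_humerus <- function() {
  fx_memo("hum_s", make_distal_humerus(small_params()))
}

# Five-frame fixed-axis sequence at coarse resolution.
small_sequence <- function() {
  fx_memo("seq_s", {
    traj <- axis_trajectory(flexion_angles = seq(0, 100, length.out = 5))
    pose_sequence(small_ulna(), traj, small_humerus()$truth)
  })
}

# Full-resolution 30-frame sequences used by the acceptance checks.
acceptance_parts <- function() {
  fx_memo("acc_parts", {
    p <- elbow_params()
    list(params = p, hum = make_distal_humerus(p),
         ulna = make_proximal_ulna(p))
  })
}

acceptance_fixed_sequence <- function() {
  fx_memo("acc_fixed", {
    ap <- acceptance_parts()
    pose_sequence(ap$ulna, axis_trajectory(), ap$hum$truth)
  })
}

# Independent brute-force circle-fit oracle: dense center grid, radius =
# mean distance, objective = summed squared radial error; two refinement
# passes around the best cell.
grid_circle_oracle <- function(u, v, n_grid = 61L, passes = 4L) {
  cu <- mean(u); cv <- mean(v)
  span <- 3 * max(diff(range(u)), diff(range(v)))
  for (p in seq_len(passes)) {
    us <- seq(cu - span, cu + span, length.out = n_grid)
    vs <- seq(cv - span, cv + span, length.out = n_grid)
    best <- Inf
    for (a in us) {
      for (b in vs) {
        d <- sqrt((u - a)^2 + (v - b)^2)
        obj <- sum((d - mean(d))^2)
        if (obj < best) {
          best <- obj; cu_b <- a; cv_b <- b
        }
      }
    }
    cu <- cu_b; cv <- cv_b
    span <- span * 4 / n_grid
  }
  d <- sqrt((u - cu)^2 + (v - cv)^2)
  list(center = c(cu, cv), radius = mean(d))
}

# Normalized ground-truth intersection of a true axis with an aspect plane.
truth_intersection_pct <- function(frame_truth, aspect) {
  p <- line_plane_intersection(frame_truth$axis_point, frame_truth$axis_dir,
                               plane3(aspect$center, aspect$normal))
  rel <- p - as.numeric(aspect$center)
  # synthetic frame axes are the world axes: Y = (0,1,0), Z = (0,0,1)
  c(y_pct = 100 * rel[2L] / aspect$radius,
    z_pct = 100 * rel[3L] / aspect$radius)
}

random_rigid <- function() {
  rigid_transform(elbowaxis:::random_rotation(), stats::rnorm(3L, sd = 30))
}
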