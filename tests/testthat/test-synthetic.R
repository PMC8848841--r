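test_that("generator emits its stated aspect geometry", {
  p <- elbow_params(medial_aspect_radius = 10, lateral_aspect_radius = 8,
                    transcondylar_length = 40, mesh_resolution = 0.9)
  hum <- make_distal_humerus(p)
  expect_equal(hum$truth$medial_aspect$radius, 10)
  expect_equal(vnorm(hum$truth$lateral_aspect$center -
                       hum$truth$medial_aspect$center), 40)
  expect_true(is_watertight(hum$mesh))
  expect_gt(mesh_volume(hum$mesh), 0)  # outward-consistent winding
})

test_that("parameter validation rejects degenerate geometry", {
  expect_error(elbow_params(notch_arc = 0), "notch_arc")
  expect_error(elbow_params(notch_arc = 360), "notch_arc")
  expect_error(elbow_params(notch_radius = -1), "positive")
  expect_error(elbow_params(mesh_resolution = 5), "mesh_resolution")
  expect_error(make_distal_humerus(
    elbow_params(medial_aspect_radius = 5, lateral_aspect_radius = 5,
                 notch_radius = 30, mesh_resolution = 4)), "coarse")
})

test_that("notch surface is an exact cylinder arc with on-surface landmarks", {
  p <- small_params()
  uln <- small_ulna()
  d <- point_line_distance(uln$mesh$vertices, uln$notch_axis$point,
                           uln$notch_axis$dir)
  on_notch <- abs(d - p$notch_radius) < 1e-9
  expect_gt(sum(on_notch), 100)  # the whole inner grid sits at radius r
  lm <- uln$landmarks
  expect_equal(point_line_distance(lm, uln$notch_axis$point,
                                   uln$notch_axis$dir),
               rep(p$notch_radius, 3L), tolerance = 1e-12)
  area2 <- vnorm(vcross(lm[2L, ] - lm[1L, ], lm[3L, ] - lm[1L, ]))
  expect_gt(area2 / 2, 1)  # non-collinear
})

test_that("posing is rigid, identity at zero, and matches a registration oracle", {
  uln <- small_ulna()
  hum <- small_humerus()
  traj0 <- axis_trajectory(flexion_angles = 0)
  ps0 <- pose_sequence(uln, traj0, hum$truth)
  expect_identical(ps0$meshes[[1L]]$vertices, uln$mesh$vertices)

  ps <- small_sequence()
  ref <- edge_lengths(uln$mesh)
  for (k in seq_along(ps$meshes)) {
    expect_lt(max(abs(edge_lengths(ps$meshes[[k]]) - ref)), 1e-9)
  }
  # relative motion frame 1 -> 2 recovered by point-set registration
  or <- helical_axis_oracle(ps$meshes[[1L]], ps$meshes[[2L]])
  expect_equal(or$angle_deg, 25, tolerance = 1e-9)
  expect_lt(line_angle(or$direction, c(1, 0, 0)), 1e-7)
})

test_that("stored ground truth reproduces the drift functions exactly", {
  uln <- small_ulna(); hum <- small_humerus()
  hdrift <- function(a) 45 * a / 100
  traj <- axis_trajectory(flexion_angles = seq(0, 100, length.out = 6),
                          horizontal_drift = hdrift)
  ps <- pose_sequence(uln, traj, hum$truth)
  for (k in seq_along(ps$truth$frames)) {
    fr <- ps$truth$frames[[k]]
    d <- fr$axis_dir
    expect_equal(atan2(d[3L], d[1L]) * 180 / pi, hdrift(fr$flexion_deg),
                 tolerance = 1e-9)
    expect_equal(vnorm(d), 1, tolerance = 1e-12)
  }
})

test_that("consecutive-frame helical axes match the stored fixed axis", {
  ps <- small_sequence()
  for (k in seq_len(length(ps$meshes) - 1L)) {
    or <- helical_axis_oracle(ps$meshes[[k]], ps$meshes[[k + 1L]])
    fr <- ps$truth$frames[[k + 1L]]
    expect_lt(line_angle(or$direction, fr$axis_dir) * pi / 180, 1e-6)
    expect_lt(point_line_distance(matrix(or$point, 1L), fr$axis_point,
                                  fr$axis_dir), 1e-6)
  }
})

test_that("vertex noise is seeded, unbiased, and chi(3)-distributed in norm", {
  mesh <- small_ulna()$mesh
  expect_identical(add_vertex_noise(mesh, 0, 1), mesh)
  n1 <- add_vertex_noise(mesh, 0.3, 11)
  n2 <- add_vertex_noise(mesh, 0.3, 11)
  expect_identical(n1$vertices, n2$vertices)
  expect_false(identical(n1$vertices,
                         add_vertex_noise(mesh, 0.3, 12)$vertices))
  # displacement magnitude: chi(3) mean = sigma * sqrt(8 / pi)
  nv <- 2e4
  big <- trimesh(matrix(0, nv, 3L), matrix(c(1L, 2L, 3L), 1L))
  noisy <- add_vertex_noise(big, 0.2, 99)
  mags <- sqrt(rowSums(noisy$vertices^2))
  expect_equal(mean(mags), 0.2 * sqrt(8 / pi), tolerance = 0.05)
})

test_that("fixtures round-trip losslessly and are byte-deterministic", {
  ps <- small_sequence(); hum <- small_humerus()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(d1, ps, hum)
  write_fixture(d2, ps, hum)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  fx <- read_fixture(d1)
  expect_length(fx$meshes, length(ps$meshes))
  expect_lt(max(abs(fx$meshes[[3L]]$vertices - ps$meshes[[3L]]$vertices)),
            1e-4)
  expect_lt(max(abs(fx$landmarks[[2L]] - ps$landmarks[[2L]])), 1e-12)
  for (fr in fx$truth$frames) expect_equal(vnorm(fr$axis_dir), 1,
                                           tolerance = 1e-12)
  expect_error(write_fixture(withr::local_tempdir(),
                             list(meshes = list()), hum),
               "at least one frame")
})
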