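test_that("landmark plane contains its landmarks and rejects collinearity", {
  pl <- plane_from_landmarks(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_error(plane_from_landmarks(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  set.seed(3)
  for (i in 1:20) {
    pts <- matrix(rnorm(9, sd = 10), 3L)
    ok <- tryCatch(plane_from_landmarks(pts[1L, ], pts[2L, ], pts[3L, ]),
                   error = function(e) NULL)
    if (!is.null(ok)) {
      expect_lt(max(abs(elbowaxis:::plane_signed_distance(ok, pts))), 1e-9)
    }
  }
})

test_that("offset planes are parallel, centered, and validated", {
  base <- plane3(c(0, 0, 0), c(0, 0, 1))
  pls <- offset_planes(base, c(0, 0, 1), spacing = 1, count = 11L)
  zs <- vapply(pls, function(p) p$point[3L], numeric(1L))
  expect_equal(zs, -5:5)
  for (p in pls) expect_equal(p$normal, base$normal)
  expect_error(offset_planes(base, c(0, 0, 1), count = 1L), ">= 2")
  expect_error(offset_planes(base, c(0, 0, 1), spacing = 0), "> 0")
})

test_that("section curves select the near cortex and stay planar", {
  # a true cylinder: frustum with equal end radii
  p <- elbow_params(medial_aspect_radius = 10, lateral_aspect_radius = 10,
                    mesh_resolution = 0.9)
  cyl <- make_distal_humerus(p)$mesh
  xs <- sort(unique(cyl$vertices[, 1L]))
  x0 <- xs[ceiling(length(xs) / 2)]   # plane through a vertex ring
  crv <- section_curve(cyl, plane3(c(x0, 0, 0), c(1, 0, 0)),
                       near = c(x0, 10, 0))
  expect_true(crv$closed)
  d <- point_line_distance(crv$points, c(0, 0, 0), c(1, 0, 0))
  expect_lt(max(abs(d - 10)), 1e-6 * 10)
  expect_error(section_curve(cyl, plane3(c(200, 0, 0), c(1, 0, 0)),
                             near = c(0, 0, 0)), "does not intersect")
  # notch section of the synthetic ulna lies on the notch cylinder
  uln <- small_ulna()
  pr <- small_params()
  crv2 <- section_curve(uln$mesh, plane3(uln$notch_axis$point, c(1, 0, 0)),
                        near = colMeans(uln$landmarks),
                        seed_circle = list(center = uln$notch_axis$point,
                                           radius = pr$notch_radius),
                        trim_tol = 0.05)
  d2 <- point_line_distance(crv2$points, uln$notch_axis$point,
                            uln$notch_axis$dir)
  expect_lt(max(abs(d2 - pr$notch_radius)), pr$mesh_resolution)
})

test_that("circle fit is exact on circles and arcs, guarded on slivers", {
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  full <- cbind(3 + 12 * cos(th), 4 + 12 * sin(th), 0)
  cf <- fit_circle(full, plane = pl)
  expect_equal(cf$center, c(3, 4, 0), tolerance = 1e-9)
  expect_equal(cf$radius, 12, tolerance = 1e-9)
  expect_lt(cf$rms_residual, 1e-9)
  semi <- full[1:50, ]
  cfs <- fit_circle(semi, plane = pl)
  expect_equal(cfs$center, c(3, 4, 0), tolerance = 1e-9)
  expect_equal(cfs$radius, 12, tolerance = 1e-9)
  sliver <- cbind(3 + 12 * cos(seq(0, 0.5, length.out = 20)),
                  4 + 12 * sin(seq(0, 0.5, length.out = 20)), 0)
  expect_error(fit_circle(sliver, plane = pl), "ill-conditioned arc")
  expect_error(fit_circle(full[1:5, ], plane = pl), ">= 8")
})

test_that("noisy-arc circle fit matches a grid-search oracle", {
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  set.seed(41)
  th <- seq(0.3, 2.4, length.out = 20)
  u <- 3 + 12 * cos(th) + rnorm(20, sd = 0.1)
  v <- 4 + 12 * sin(th) + rnorm(20, sd = 0.1)
  cf <- fit_circle(cbind(u, v, 0), plane = pl)
  oracle <- grid_circle_oracle(u, v)
  expect_lt(vnorm(cf$center[1:2] - oracle$center), 0.15)
})

test_that("axis fit recovers lines and flags degeneracy", {
  d <- c(1, 1, 0) / sqrt(2)
  pts <- t(sapply(seq(-5, 5), function(s) s * d))
  ax <- fit_axis(pts, lateral_dir = NULL)
  expect_lt(line_angle(ax$direction, d), 1e-9)
  expect_lt(ax$rms_residual, 1e-12)
  expect_error(fit_axis(pts[c(1, 1, 1), ]), "degenerate")
  expect_error(fit_axis(pts * 1e-4), "degenerate")
  set.seed(5)
  noisy <- pts + matrix(rnorm(33, sd = 0.05), ncol = 3L)
  axn <- fit_axis(noisy, lateral_dir = c(1, 0, 0))
  expect_lt(line_angle(axn$direction, d), 0.5)
  expect_gt(sum(axn$direction * c(1, 0, 0)), 0)  # sign convention
})

test_that("notch estimator recovers the ground-truth axis", {
  uln <- small_ulna()
  truth <- uln$notch_axis
  ax <- estimate_instantaneous_axis(uln$mesh, uln$landmarks)
  expect_lt(line_angle(ax$direction, truth$dir), 0.1)
  expect_lt(point_line_distance(matrix(ax$point, 1L), truth$point,
                                truth$dir), 0.1)
  expect_identical(nrow(ax$diagnostics), 11L)
  # the axis rides with the bone under a 40 deg flexion about itself
  tf <- elbowaxis:::rigid_about_axis(truth$point, truth$dir, 40)
  ax2 <- estimate_instantaneous_axis(transform_mesh(uln$mesh, tf),
                                     apply_rigid(tf, uln$landmarks))
  expect_lt(line_angle(ax2$direction, truth$dir), 0.1)
  expect_lt(point_line_distance(matrix(ax2$point, 1L), truth$point,
                                truth$dir), 0.1)
})

test_that("estimator tolerates seeded landmark jitter", {
  uln <- small_ulna()
  jit <- elbowaxis:::with_seed(202, matrix(rnorm(9, sd = 0.5), 3L))
  ax <- estimate_instantaneous_axis(uln$mesh, uln$landmarks + jit,
                                    config = list(surface_tol = 3))
  expect_lt(line_angle(ax$direction, uln$notch_axis$dir), 2)
})

test_that("estimate is rigid-equivariant and offset-direction symmetric", {
  uln <- small_ulna()
  ax0 <- estimate_instantaneous_axis(uln$mesh, uln$landmarks)
  set.seed(17)
  tf <- random_rigid()
  axT <- estimate_instantaneous_axis(transform_mesh(uln$mesh, tf),
                                     apply_rigid(tf, uln$landmarks),
                                     config = list(lateral_dir = NULL))
  # equivariance is exact up to curve re-selection at trim boundaries,
  # which can flip single section points under reoriented rounding
  expect_lt(line_angle(axT$direction, as.numeric(tf$R %*% ax0$direction)),
            1e-3)
  expect_lt(point_line_distance(matrix(apply_rigid(tf, ax0$point), 1L),
                                axT$point, axT$direction), 1e-3)
  # reversing the offset direction spans the same planes, hence same line
  base <- plane_from_landmarks(uln$landmarks[1L, ], uln$landmarks[2L, ],
                               uln$landmarks[3L, ])
  fwd <- offset_planes(base, base$normal, 1, 11L)
  rev_ <- offset_planes(base, -base$normal, 1, 11L)
  off_f <- sort(vapply(fwd, function(p)
    sum((p$point - base$point) * base$normal), numeric(1L)))
  off_r <- sort(vapply(rev_, function(p)
    sum((p$point - base$point) * base$normal), numeric(1L)))
  expect_equal(off_f, off_r, tolerance = 1e-12)
})

test_that("helical axis oracle is exact and flags tiny rotations", {
  uln <- small_ulna()
  tf <- elbowaxis:::rigid_about_axis(c(10, 5, -2), c(0, 1, 1), 30)
  or <- helical_axis_oracle(uln$mesh, transform_mesh(uln$mesh, tf))
  expect_equal(or$angle_deg, 30, tolerance = 1e-9)
  expect_lt(line_angle(or$direction, c(0, 1, 1)) * pi / 180, 1e-9)
  expect_lt(point_line_distance(matrix(or$point, 1L), c(10, 5, -2),
                                c(0, 1, 1)), 1e-6)
  expect_true(helical_axis_oracle(uln$mesh, uln$mesh)$unreliable)
  # noisy correspondences
  noisy <- add_vertex_noise(transform_mesh(uln$mesh, tf), 0.1, 8)
  orn <- helical_axis_oracle(uln$mesh, noisy)
  expect_lt(line_angle(orn$direction, c(0, 1, 1)), 0.5)
  expect_error(helical_axis_oracle(uln$mesh,
                                   trimesh(uln$mesh$vertices[1:10, ],
                                           matrix(c(1L, 2L, 3L), 1L))),
               "vertex-corresponding")
})
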