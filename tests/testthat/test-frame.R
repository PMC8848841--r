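test_that("aspect circle fitting recovers exact and synthetic rims", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  rim <- cbind(0, 10 * cos(th), 3 + 10 * sin(th))
  ac <- fit_aspect_circle(rim, side = "medial")
  expect_equal(ac$center, c(0, 0, 3), tolerance = 1e-9)
  expect_equal(ac$radius, 10, tolerance = 1e-9)
  expect_equal(abs(ac$normal), c(1, 0, 0), tolerance = 1e-9)
  expect_error(fit_aspect_circle(rim[1:3, ]), ">= 8")
  expect_error(fit_aspect_circle(cbind(1:10, 2 * (1:10), 3 * (1:10))),
               "collinear")
  truth <- small_humerus()$truth
  rim2 <- elbowaxis:::aspect_rim_points(truth$lateral_aspect, 16L)
  ac2 <- fit_aspect_circle(rim2, side = "lateral")
  expect_equal(ac2$center, truth$lateral_aspect$center, tolerance = 1e-9)
  expect_equal(ac2$radius, truth$lateral_aspect$radius, tolerance = 1e-9)
})

test_that("frame construction follows the stated axis conventions", {
  med <- aspect_circle("medial", c(0, 0, 0), 10, c(1, 0, 0))
  lat <- aspect_circle("lateral", c(50, 0, 0), 8, c(1, 0, 0))
  fr <- build_frame(med, lat, shaft_dir = c(0, 1, 0),
                    posterior_hint = c(0, 0, 1))
  expect_equal(fr$X, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$Y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$Z, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(vcross(fr$X, fr$Y), fr$Z, tolerance = 1e-12)
  # shaft tilted 10 deg in XY: Z must stay perpendicular to X and shaft
  shaft <- c(sin(10 * pi / 180), cos(10 * pi / 180), 0)
  fr2 <- build_frame(med, lat, shaft_dir = shaft)
  expect_equal(fr2$Z, c(0, 0, 1), tolerance = 1e-12)
  G <- rbind(fr2$X, fr2$Y, fr2$Z)
  expect_lt(max(abs(G %*% t(G) - diag(3L))), 1e-12)
  expect_error(build_frame(med, lat, shaft_dir = c(1, 0, 0)),
               "degenerate shaft")
  # origin projection onto the humerus surface
  fr3 <- build_frame(med, lat, shaft_dir = c(0, 1, 0),
                     humerus_mesh = small_humerus()$mesh)
  expect_equal(fr3$origin, c(0, 0, 0), tolerance = 1e-9)
  # left side mirrors X and stays right-handed
  frl <- build_frame(med, lat, shaft_dir = c(0, 1, 0), side = "left")
  expect_equal(frl$X, c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(vcross(frl$X, frl$Y), frl$Z, tolerance = 1e-12)
})

test_that("frames are orthonormal right-handed and rigid-equivariant", {
  set.seed(11)
  for (i in 1:25) {
    med <- aspect_circle("medial", rnorm(3, sd = 20), runif(1, 5, 15),
                         c(1, 0, 0))
    lat <- aspect_circle("lateral", med$center + c(50, rnorm(2, sd = 5)),
                         runif(1, 5, 15), c(1, 0, 0))
    shaft <- unitv(c(rnorm(1, sd = 0.2), 1, rnorm(1, sd = 0.2)))
    fr <- build_frame(med, lat, shaft)
    G <- rbind(fr$X, fr$Y, fr$Z)
    expect_lt(max(abs(G %*% t(G) - diag(3L))), 1e-9)
    expect_equal(vcross(fr$X, fr$Y), fr$Z, tolerance = 1e-9)
    tf <- random_rigid()
    frT <- build_frame(
      aspect_circle("medial", apply_rigid(tf, med$center), med$radius,
                    as.numeric(tf$R %*% med$normal)),
      aspect_circle("lateral", apply_rigid(tf, lat$center), lat$radius,
                    as.numeric(tf$R %*% lat$normal)),
      as.numeric(tf$R %*% shaft),
      posterior_hint = as.numeric(tf$R %*% c(0, 0, 1)))
    expect_equal(frT$origin, apply_rigid(tf, fr$origin), tolerance = 1e-9)
    for (axn in c("X", "Y", "Z")) {
      expect_equal(frT[[axn]], as.numeric(tf$R %*% fr[[axn]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("flexion angle recovers the posed sequence", {
  hum_pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  expect_equal(flexion_angle(hum_pl, hum_pl)$angle, 0)
  perp <- plane3(c(0, 0, 0), c(0, 1, 0))
  expect_equal(flexion_angle(perp, hum_pl)$angle, 90)
  ps <- small_sequence()
  for (k in seq_along(ps$ulna_planes)) {
    fa <- flexion_angle(ps$ulna_planes[[k]], hum_pl, axis_x = c(1, 0, 0))
    expect_equal(fa$angle, ps$truth$frames[[k]]$flexion_deg,
                 tolerance = 0.5)
  }
})

test_that("frame coordinates round-trip", {
  med <- aspect_circle("medial", c(1, 2, 3), 10, c(1, 0, 0))
  lat <- aspect_circle("lateral", c(45, 9, -2), 8, c(1, 0, 0))
  fr <- build_frame(med, lat, shaft_dir = c(0.1, 1, 0.05))
  expect_equal(to_frame_coords(fr$origin, fr), c(x = 0, y = 0, z = 0),
               tolerance = 1e-12)
  expect_equal(to_frame_coords(fr$origin + 5 * fr$Z, fr),
               c(x = 0, y = 0, z = 5), tolerance = 1e-12)
  set.seed(2)
  pts <- matrix(rnorm(30, sd = 40), ncol = 3L)
  expect_equal(from_frame_coords(to_frame_coords(pts, fr), fr), pts,
               tolerance = 1e-12, ignore_attr = TRUE)
})
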