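ref_frame <- function() {
  build_frame(aspect_circle("medial", c(0, 0, 0), 10, c(1, 0, 0)),
              aspect_circle("lateral", c(50, 0, 0), 8, c(1, 0, 0)),
              shaft_dir = c(0, 1, 0))
}

test_that("axis-aspect intersection matches the closed form", {
  med <- aspect_circle("medial", c(-1, 0, 0), 10, c(1, 0, 0))
  ax <- rotation_axis(c(0, 0, 0), c(1, 0, 0))
  expect_equal(intersect_axis_with_aspect(ax, med), c(-1, 0, 0),
               tolerance = 1e-12)
  in_plane <- rotation_axis(c(-1, 0, 0), c(0, 1, 0))
  expect_error(intersect_axis_with_aspect(in_plane, med), "parallel")
  # generator truth vs analytic line-plane intersection
  ps <- small_sequence()
  tru <- ps$truth
  for (fr in tru$frames) {
    ax2 <- rotation_axis(fr$axis_point, fr$axis_dir)
    p <- intersect_axis_with_aspect(
      ax2, aspect_circle("medial", tru$medial_aspect$center,
                         tru$medial_aspect$radius,
                         tru$medial_aspect$normal))
    s <- sum((p - tru$medial_aspect$center) * tru$medial_aspect$normal)
    expect_lt(abs(s), 1e-9)                    # on the plane
    expect_lt(point_line_distance(matrix(p, 1L), fr$axis_point,
                                  fr$axis_dir), 1e-9)  # on the line
  }
})

test_that("normalization is radius-relative on the stated reference", {
  fr <- ref_frame()
  med <- aspect_circle("medial", c(0, 0, 0), 10, c(1, 0, 0))
  lat <- aspect_circle("lateral", c(50, 0, 0), 8, c(1, 0, 0))
  expect_equal(normalize_intersection(med$center, fr, med),
               c(y_pct = 0, z_pct = 0))
  expect_equal(normalize_intersection(med$center + 10 * fr$Z, fr, med),
               c(y_pct = 0, z_pct = 100))
  expect_equal(normalize_intersection(med$center + 5 * fr$Y - 2.5 * fr$Z,
                                      fr, med),
               c(y_pct = 50, z_pct = -25))
  # lateral side referenced to the lateral center by default
  expect_equal(normalize_intersection(lat$center + 4 * fr$Y, fr, lat),
               c(y_pct = 50, z_pct = 0))
  expect_equal(normalize_intersection(lat$center + 4 * fr$Y, fr, lat,
                                      lateral_origin = "frame_origin"),
               c(y_pct = 50, z_pct = 0))  # here centers share Y/Z coords
})

test_that("quadrants follow coordinate signs with a flagged tie rule", {
  expect_equal(as.character(classify_quadrant(10, 5)), "posterior-superior")
  expect_equal(as.character(classify_quadrant(-30, -2)), "anterior-inferior")
  expect_equal(as.character(classify_quadrant(3, -1)), "anterior-superior")
  expect_equal(as.character(classify_quadrant(-3, 1)), "posterior-inferior")
  q <- classify_quadrant(0, 0)
  expect_equal(as.character(q), "posterior-superior")
  expect_true(attr(q, "tie"))
  expect_false(attr(classify_quadrant(1, 1), "tie"))
})

test_that("axis angles decompose into coronal and horizontal projections", {
  fr <- ref_frame()
  ax <- function(d) rotation_axis(c(0, 0, 0), d)
  a1 <- axis_angles(ax(c(1, 0, 0)), fr)
  expect_equal(c(a1$coronal_deg, a1$horizontal_deg), c(0, 0))
  a2 <- axis_angles(ax(c(1, 0, 1) / sqrt(2)), fr)
  expect_equal(c(a2$coronal_deg, a2$horizontal_deg), c(0, 45))
  a3 <- axis_angles(ax(c(1, 1, 0) / sqrt(2)), fr)
  expect_equal(c(a3$coronal_deg, a3$horizontal_deg), c(45, 0))
  a4 <- axis_angles(ax(c(1, -1, 0) / sqrt(2)), fr)
  expect_equal(a4$coronal_deg, 45)
  expect_equal(a4$coronal_signed_deg, -45)
  expect_error(axis_angles(ax(c(0, 1, 0)), fr), "undefined")
})

test_that("the isometric window needs both sides within threshold", {
  df <- data.frame(
    frame = c(1, 1, 2, 2),
    side = c("medial", "lateral", "medial", "lateral"),
    y_pct = c(10, 15, 10, 21),
    z_pct = c(-5, 19, -5, 0),
    flexion_deg = c(5, 5, 40, 40))
  w <- isometric_window(df, threshold_pct = 20)
  expect_identical(w$selected_frames, 1L)
  expect_equal(w$flexion_range, c(5, 5))
  expect_error(isometric_window(df[df$side == "medial", ]), "both sides")
})

test_that("normalized coordinates and angles are scale-equivariant", {
  fr <- ref_frame()
  med <- aspect_circle("medial", c(0, 0, 0), 10, c(1, 0, 0))
  ax <- rotation_axis(c(25, 1.3, -0.4), unitv(c(1, 0.1, -0.2)))
  p1 <- intersect_axis_with_aspect(ax, med)
  n1 <- normalize_intersection(p1, fr, med)
  a1 <- axis_angles(ax, fr)
  # double every length
  fr2 <- build_frame(aspect_circle("medial", c(0, 0, 0), 20, c(1, 0, 0)),
                     aspect_circle("lateral", c(100, 0, 0), 16, c(1, 0, 0)),
                     shaft_dir = c(0, 1, 0))
  med2 <- aspect_circle("medial", c(0, 0, 0), 20, c(1, 0, 0))
  ax2 <- rotation_axis(2 * ax$point, ax$direction)
  p2 <- intersect_axis_with_aspect(ax2, med2)
  n2 <- normalize_intersection(p2, fr2, med2)
  a2 <- axis_angles(ax2, fr2)
  expect_equal(n2, n1, tolerance = 1e-12)
  expect_equal(a2$coronal_deg, a1$coronal_deg, tolerance = 1e-12)
  expect_equal(a2$horizontal_deg, a1$horizontal_deg, tolerance = 1e-12)
  expect_identical(as.character(classify_quadrant(n2[1L], n2[2L])),
                   as.character(classify_quadrant(n1[1L], n1[2L])))
})

test_that("drifting ground truth produces monotone intersection migration", {
  # axis tilting in the horizontal plane and climbing superiorly
  traj <- axis_trajectory(flexion_angles = seq(0, 106.5, length.out = 8),
                          horizontal_drift = function(a) -47 * (a / 106.5)^3,
                          axis_point_offset = function(a)
                            c(0, 5.7 * a / 106.5, 0))
  hum <- small_humerus()$truth
  med_z <- lat_z <- med_y <- lat_y <- numeric(0)
  for (a in traj$flexion_angles) {
    d <- elbowaxis:::axis_direction_from_drift(0, traj$horizontal_drift(a))
    p <- c(25, 0, 0) + traj$axis_point_offset(a)
    ft <- list(axis_point = p, axis_dir = d)
    m <- truth_intersection_pct(ft, hum$medial_aspect)
    l <- truth_intersection_pct(ft, hum$lateral_aspect)
    med_z <- c(med_z, m[["z_pct"]]); med_y <- c(med_y, m[["y_pct"]])
    lat_z <- c(lat_z, l[["z_pct"]]); lat_y <- c(lat_y, l[["y_pct"]])
  }
  expect_true(all(diff(med_z) > 0))   # medial: toward posterior
  expect_true(all(diff(med_y) > 0))   # medial: toward superior
  expect_true(all(diff(lat_z) < 0))   # lateral: toward anterior
  expect_true(all(diff(lat_y) > 0))   # lateral: toward superior
})
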