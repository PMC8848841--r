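# Where the rotation axis pierces the epicondylar aspects: line-plane
# intersection, radius-normalized (y%, z%) coordinates, quadrant labels,
# axis/transcondylar angles in the coronal and horizontal planes, and the
# +/-20% isometric window of frames.

#' Intersection of the rotation axis with an aspect plane
#'
#' @param axis `rotation_axis`.
#' @param aspect `aspect_circle` (its plane is the target; the "aspect" is
#'   a near-planar face).
#' @return 3-vector (mm).
#' @export
intersect_axis_with_aspect <- function(axis, aspect) {
  line_plane_intersection(axis$point, axis$direction,
                          plane3(aspect$center, aspect$normal))
}

#' Radius-normalized intersection coordinates
#'
#' Y and Z frame-coordinates of the pierce point divided by the aspect
#' radius, in percent. The medial side is referenced to the frame origin
#' (the projected medial aspect center); the lateral side to the lateral
#' aspect center expressed on the same frame axes.
#'
#' @param point 3-vector (mm), e.g. from [intersect_axis_with_aspect()].
#' @param frame `humerus_frame`.
#' @param aspect `aspect_circle`.
#' @param lateral_origin `"lateral_center"` (default) or `"frame_origin"`:
#'   reference used for the lateral side.
#' @return named vector `c(y_pct, z_pct)`.
#' @export
normalize_intersection <- function(point, frame, aspect,
                                   lateral_origin = c("lateral_center",
                                                      "frame_origin")) {
  lateral_origin <- match.arg(lateral_origin)
  if (aspect$radius <= 0) stop("aspect radius must be > 0", call. = FALSE)
  ref <- if (aspect$side == "lateral" && lateral_origin == "lateral_center") {
    as.numeric(aspect$center)
  } else {
    frame$origin
  }
  rel <- as.numeric(point) - ref
  c(y_pct = 100 * sum(rel * frame$Y) / aspect$radius,
    z_pct = 100 * sum(rel * frame$Z) / aspect$radius)
}

#' Quadrant of a normalized intersection
#'
#' Posterior/anterior from the sign of `z_pct`, superior/inferior from the
#' sign of `y_pct`. Exact zeros fall in the positive class
#' (posterior/superior) and are flagged as ties.
#'
#' @param y_pct,z_pct normalized coordinates (percent).
#' @return character scalar, one of `"anterior-superior"`,
#'   `"posterior-superior"`, `"anterior-inferior"`, `"posterior-inferior"`,
#'   with attribute `tie` when a coordinate was exactly zero.
#' @export
classify_quadrant <- function(y_pct, z_pct) {
  ap <- if (z_pct >= 0) "posterior" else "anterior"
  si <- if (y_pct >= 0) "superior" else "inferior"
  out <- paste(ap, si, sep = "-")
  attr(out, "tie") <- (y_pct == 0) || (z_pct == 0)
  out
}

#' Axis angles against the transcondylar axis
#'
#' Signed angle between the frame X axis and the rotation axis direction
#' after projection into the coronal (XY) and horizontal (XZ) planes;
#' reported unsigned in `[0, 90]` with the signed values retained.
#'
#' @param axis `rotation_axis`.
#' @param frame `humerus_frame`.
#' @param frame_index bookkeeping index.
#' @return list of class `axis_angles`: `coronal_deg`, `horizontal_deg`
#'   (unsigned), `coronal_signed_deg`, `horizontal_signed_deg`.
#' @export
axis_angles <- function(axis, frame, frame_index = NA_integer_) {
  d <- axis$direction
  dx <- sum(d * frame$X); dy <- sum(d * frame$Y); dz <- sum(d * frame$Z)
  if (sqrt(dx^2 + dy^2) < 1e-9 || sqrt(dx^2 + dz^2) < 1e-9) {
    stop("axis is perpendicular to a projection plane; angle undefined",
         call. = FALSE)
  }
  cor_s <- rad2deg(atan2(dy, dx))
  hor_s <- rad2deg(atan2(dz, dx))
  structure(list(frame_index = frame_index,
                 coronal_deg = abs(cor_s), horizontal_deg = abs(hor_s),
                 coronal_signed_deg = cor_s, horizontal_signed_deg = hor_s),
            class = "axis_angles")
}

#' Frames whose axis stays near both aspect centers
#'
#' Selects the frames where the normalized intersection lies within
#' `threshold_pct` of the aspect center on Y and Z simultaneously on both
#' the medial and the lateral side.
#'
#' @param intersections data.frame with columns `frame`, `side`
#'   (medial/lateral), `y_pct`, `z_pct` and optionally `flexion_deg`.
#' @param threshold_pct half-width of the window (percent of the aspect
#'   radius).
#' @return list with `threshold_pct`, `selected_frames` (integer vector)
#'   and `flexion_range` (range of the selected frames' flexion angles, or
#'   NULL when unavailable).
#' @export
isometric_window <- function(intersections, threshold_pct = 20) {
  stopifnot(all(c("frame", "side", "y_pct", "z_pct") %in%
                  colnames(intersections)))
  ok <- abs(intersections$y_pct) <= threshold_pct &
    abs(intersections$z_pct) <= threshold_pct
  agg <- tapply(ok, intersections$frame, all)
  sides <- tapply(intersections$side, intersections$frame,
                  function(s) all(c("medial", "lateral") %in% s))
  if (!all(sides)) {
    stop("both sides must be present for every frame", call. = FALSE)
  }
  selected <- as.integer(names(agg))[agg]
  fr <- NULL
  if ("flexion_deg" %in% colnames(intersections) && length(selected) > 0L) {
    sub <- intersections[intersections$frame %in% selected, ]
    fr <- range(sub$flexion_deg)
  }
  list(threshold_pct = threshold_pct, selected_frames = sort(selected),
       flexion_range = fr)
}

#' Scatter plot of normalized intersections on an aspect disk
#'
#' A Figs-style summary: intersections within the unit (100%) disk of one
#' aspect, colored by flexion angle.
#'
#' @param intersections data.frame as in [isometric_window()].
#' @param side `"medial"` or `"lateral"`.
#' @return a ggplot object.
#' @export
plot_intersections <- function(intersections, side = c("medial", "lateral")) {
  side <- match.arg(side)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_intersections requires ggplot2", call. = FALSE)
  }
  sub <- intersections[intersections$side == side, ]
  circ <- data.frame(z_pct = 100 * cos(seq(0, 2 * pi, length.out = 181)),
                     y_pct = 100 * sin(seq(0, 2 * pi, length.out = 181)))
  ggplot2::ggplot(sub, ggplot2::aes(x = z_pct, y = y_pct)) +
    ggplot2::geom_path(data = circ, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(colour = flexion_deg)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Z / aspect radius (%)", y = "Y / aspect radius (%)",
                  colour = "flexion (deg)",
                  title = paste(side, "aspect intersections"))
}
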