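# Landmark coordinate system of the distal humerus and per-frame flexion
# angles. Conventions (right elbow): X along the transcondylar line toward
# lateral, Y toward superior (approximately the shaft), Z toward posterior;
# origin at the projection of the medial aspect center onto the medial
# epicondyle surface.

#' Fit an epicondylar aspect circle to rim points
#'
#' Total-least-squares plane through the rim points, then the in-plane
#' least-squares circle (same engine as [fit_circle()]).
#'
#' @param rim_points n x 3 matrix (n >= 8) of points on the aspect rim.
#' @param side `"medial"` or `"lateral"`.
#' @return object of class `aspect_circle`: `side`, `center`, `radius`,
#'   plane `normal`, `rms_residual`.
#' @export
fit_aspect_circle <- function(rim_points, side = c("medial", "lateral")) {
  side <- match.arg(side)
  pts <- as_points(rim_points)
  if (nrow(pts) < 8L) stop("need >= 8 rim points", call. = FALSE)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2L, ctr, "-")
  sv <- svd(rel)
  if (sv$d[2L] < 1e-9) {
    stop("rim points are collinear; cannot fit an aspect circle",
         call. = FALSE)
  }
  normal <- sv$v[, 3L]
  cf <- fit_circle(pts, plane = plane3(ctr, normal), min_arc_deg = 60)
  aspect_circle(side = side, center = cf$center, radius = cf$radius,
                normal = normal, rms_residual = cf$rms_residual)
}

#' Epicondylar aspect circle
#'
#' @param side `"medial"` or `"lateral"`.
#' @param center,radius,normal circle parameters (mm / unit normal).
#' @param rms_residual fit residual (mm).
#' @return object of class `aspect_circle`.
#' @export
aspect_circle <- function(side, center, radius, normal,
                          rms_residual = NA_real_) {
  if (radius <= 0) stop("aspect radius must be > 0", call. = FALSE)
  structure(list(side = side, center = as.numeric(center), radius = radius,
                 normal = unitv(normal), rms_residual = rms_residual),
            class = "aspect_circle")
}

#' @export
print.aspect_circle <- function(x, ...) {
  cat(sprintf("%s aspect: center (%s) mm, radius %.2f mm\n", x$side,
              paste(sprintf("%.2f", x$center), collapse = ", "), x$radius))
  invisible(x)
}

#' Build the distal-humerus landmark coordinate system
#'
#' X is the unit vector from the medial to the lateral aspect center
#' (mirrored for a left elbow); Z is the component of `X x shaft_dir`
#' oriented toward `posterior_hint`; Y = Z x X, sign-fixed toward the
#' shaft (superior). The origin is the medial aspect center projected
#' along -X onto the humerus surface (ray cast); without a mesh, or when
#' the ray misses, the medial center itself is used.
#'
#' @param medial,lateral `aspect_circle`s.
#' @param shaft_dir unit direction of the humeral long axis (superior).
#' @param posterior_hint any vector with a positive posterior component.
#' @param humerus_mesh optional `trimesh` for the origin projection.
#' @param side `"right"` (default) or `"left"`.
#' @return object of class `humerus_frame`: `origin`, unit `X`, `Y`, `Z`.
#' @export
build_frame <- function(medial, lateral, shaft_dir,
                        posterior_hint = c(0, 0, 1), humerus_mesh = NULL,
                        side = c("right", "left")) {
  side <- match.arg(side)
  mc <- as.numeric(medial$center); lc <- as.numeric(lateral$center)
  if (vnorm(lc - mc) < 1e-9) stop("aspect centers coincide", call. = FALSE)
  X <- unitv(lc - mc)
  if (side == "left") X <- -X
  shaft <- unitv(shaft_dir)
  if (line_angle(X, shaft) < 5) {
    stop("degenerate shaft: shaft direction within 5 degrees of the ",
         "transcondylar axis", call. = FALSE)
  }
  Z <- unitv(vcross(X, shaft))
  if (sum(Z * posterior_hint) < 0) Z <- -Z
  Y <- unitv(vcross(Z, X))
  if (sum(Y * shaft) < 0) {
    Y <- -Y
    Z <- vcross(X, Y)
  }
  origin <- mc
  if (!is.null(humerus_mesh)) {
    hit <- ray_mesh_intersect(humerus_mesh, mc, -X)
    if (is.null(hit)) {
      warning("origin projection ray missed the humerus mesh; ",
              "using the medial aspect center")
    } else {
      origin <- hit
    }
  }
  structure(list(origin = origin, X = X, Y = Y, Z = Z, side = side),
            class = "humerus_frame")
}

#' @export
print.humerus_frame <- function(x, ...) {
  cat("humerus frame (", x$side, " elbow)\n", sep = "")
  cat("  origin (", paste(sprintf("%.2f", x$origin), collapse = ", "),
      ") mm\n", sep = "")
  for (ax in c("X", "Y", "Z")) {
    cat("  ", ax, " (", paste(sprintf("%.4f", x[[ax]]), collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Flexion angle between the ulnar and humeral coronal planes
#'
#' The dihedral angle between the two planes. With the frame's X axis
#' supplied the rotation sense about X disambiguates the arccos fold and
#' the angle is reported in `[0, 180)`; otherwise the unsigned dihedral
#' `acos(|n1 . n2|)` in `[0, 90]` is returned.
#'
#' @param ulna_plane,humerus_plane `plane3`.
#' @param axis_x optional frame X direction.
#' @param frame_index bookkeeping index.
#' @return list of class `flexion_angle` with `angle` (deg) and
#'   `frame_index`.
#' @export
flexion_angle <- function(ulna_plane, humerus_plane, axis_x = NULL,
                          frame_index = NA_integer_) {
  n1 <- humerus_plane$normal
  n2 <- ulna_plane$normal
  if (is.null(axis_x)) {
    ang <- rad2deg(acos(pmin(1, abs(sum(n1 * n2)))))
  } else {
    x <- unitv(axis_x)
    ang <- rad2deg(atan2(sum(vcross(n1, n2) * x), sum(n1 * n2)))
    ang <- abs(ang)
    if (ang >= 180) ang <- ang - 180
  }
  structure(list(frame_index = frame_index, angle = ang),
            class = "flexion_angle")
}

#' Express a point in humerus frame coordinates
#'
#' @param point 3-vector or n x 3 matrix (world mm).
#' @param frame `humerus_frame`.
#' @return coordinates on (X, Y, Z) relative to the frame origin.
#' @export
to_frame_coords <- function(point, frame) {
  single <- is.null(dim(point))
  p <- as_points(point)
  rel <- sweep(p, 2L, frame$origin, "-")
  out <- cbind(rel %*% frame$X, rel %*% frame$Y, rel %*% frame$Z)
  colnames(out) <- c("x", "y", "z")
  if (single) {
    out <- as.numeric(out)
    names(out) <- c("x", "y", "z")
  }
  out
}

#' Map frame coordinates back to world coordinates
#'
#' Inverse of [to_frame_coords()].
#'
#' @param coords 3-vector or n x 3 matrix of frame coordinates.
#' @param frame `humerus_frame`.
#' @return world coordinates (mm).
#' @export
from_frame_coords <- function(coords, frame) {
  single <- is.null(dim(coords))
  q <- as_points(coords)
  B <- rbind(frame$X, frame$Y, frame$Z)
  out <- sweep(q %*% B, 2L, frame$origin, "+")
  if (single) as.numeric(out) else out
}
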