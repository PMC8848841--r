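# Small 3-D vector / rigid-motion toolkit shared by all modules.
# Points are length-3 numeric vectors or n x 3 matrices, units are mm.

#' Euclidean norm of a vector
#'
#' @param v numeric vector.
#' @return scalar length.
#' @export
vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a 3-vector to unit length
#'
#' @param v numeric length-3 vector.
#' @param tol vectors shorter than `tol` are rejected.
#' @return unit vector parallel to `v`.
#' @export
unitv <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}

#' Cross product of two 3-vectors
#'
#' @param a,b numeric length-3 vectors.
#' @return 3-vector `a x b`.
#' @export
vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 3L)
  p
}

#' Rotation matrix about an axis (Rodrigues formula)
#'
#' @param axis rotation axis (any nonzero 3-vector; normalized internally).
#' @param angle_deg rotation angle in degrees, right-handed about `axis`.
#' @return 3 x 3 rotation matrix.
#' @export
rot3 <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal rotation carrying unit vector a onto unit vector b.
rot_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- vcross(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-14) {
    if (c_ > 0) return(diag(3L))
    # antiparallel: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitv(vcross(a, ref))
    return(rot3(ax, 180))
  }
  K <- matrix(c(0, v[3L], -v[2L],
                -v[3L], 0, v[1L],
                v[2L], -v[1L], 0), 3L, 3L)
  diag(3L) + K + K %*% K * (1 / (1 + c_))
}

#' Rigid transform (rotation + translation)
#'
#' Represents the map `x -> R x + t`.
#'
#' @param R 3 x 3 rotation matrix.
#' @param t translation 3-vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3L), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == 3L), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3L))) > 1e-8) {
    stop("R is not orthonormal", call. = FALSE)
  }
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform, rotation angle",
      format(rad2deg(acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2)))),
             digits = 4),
      "deg, |t| =", format(vnorm(x$t), digits = 4), "mm\n")
  invisible(x)
}

# Rotation by angle_deg about the line (point, dir).
rigid_about_axis <- function(point, dir, angle_deg) {
  R <- rot3(dir, angle_deg)
  rigid_transform(R, as.numeric(point) - R %*% as.numeric(point))
}

#' Apply a rigid transform to points
#'
#' @param tf `rigid_transform`.
#' @param p 3-vector or n x 3 matrix of points.
#' @return transformed points, same shape as input.
#' @export
apply_rigid <- function(tf, p) {
  single <- is.null(dim(p))
  p <- as_points(p)
  out <- p %*% t(tf$R)
  out <- sweep(out, 2L, tf$t, "+")
  if (single) as.numeric(out) else out
}

# first %then% second (composition: apply g after f)
compose_rigid <- function(g, f) {
  rigid_transform(g$R %*% f$R, as.numeric(g$R %*% f$t) + g$t)
}

invert_rigid <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

# Uniformly random rotation (via QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Infinite plane in 3-space
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized internally.
#' @return object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unitv(normal)),
            class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat("plane through (", paste(format(x$point, digits = 4), collapse = ", "),
      ") with normal (", paste(format(x$normal, digits = 4), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Signed distances of points to a plane.
plane_signed_distance <- function(plane, p) {
  p <- as_points(p)
  as.numeric(sweep(p, 2L, plane$point, "-") %*% plane$normal)
}

# Orthonormal in-plane basis (e1, e2) with e1 x e2 = normal.
plane_basis <- function(plane) {
  n <- plane$normal
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(vcross(ref, n))
  e2 <- vcross(n, e1)
  list(e1 = e1, e2 = e2)
}

#' Intersection of a line with a plane
#'
#' @param point,dir line point and direction.
#' @param plane `plane3`.
#' @param tol parallelism guard on `|dir . normal|`.
#' @return 3-vector (mm).
#' @export
line_plane_intersection <- function(point, dir, plane, tol = 1e-6) {
  d <- unitv(dir)
  denom <- sum(d * plane$normal)
  if (abs(denom) <= tol) {
    stop("axis parallel to aspect plane", call. = FALSE)
  }
  s <- sum((plane$point - point) * plane$normal) / denom
  as.numeric(point + s * d)
}

#' Perpendicular distance of points to a line
#'
#' @param p 3-vector or n x 3 matrix.
#' @param point,dir line point and direction.
#' @return numeric vector of distances (mm).
#' @export
point_line_distance <- function(p, point, dir) {
  p <- as_points(p)
  d <- unitv(dir)
  rel <- sweep(p, 2L, as.numeric(point), "-")
  proj <- as.numeric(rel %*% d)
  sqrt(pmax(0, rowSums(rel^2) - proj^2))
}

#' Angle between two vectors
#'
#' @param a,b vectors.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_between <- function(a, b) {
  rad2deg(acos(pmin(1, pmax(-1, sum(unitv(a) * unitv(b))))))
}

#' Acute angle between two lines
#'
#' Sign-free: directions and their negations are equivalent.
#'
#' @param a,b direction vectors.
#' @return angle in degrees, in `[0, 90]`.
#' @export
line_angle <- function(a, b) {
  rad2deg(acos(pmin(1, abs(sum(unitv(a) * unitv(b))))))
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Circumcircle of three points in 3-D: center, radius and plane normal.
circumcircle3 <- function(p1, p2, p3) {
  a <- as.numeric(p1); b <- as.numeric(p2); c_ <- as.numeric(p3)
  ab <- b - a; ac <- c_ - a
  n <- vcross(ab, ac)
  n2 <- sum(n * n)
  if (n2 < 1e-12) stop("points are collinear", call. = FALSE)
  center <- a + (sum(ac * ac) * vcross(n, ab) + sum(ab * ab) * vcross(ac, n)) /
    (2 * n2)
  list(center = center, radius = vnorm(center - a), normal = unitv(n))
}
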