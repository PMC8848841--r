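# Instantaneous rotation axis estimation from the greater sigmoid notch:
# landmark plane -> offset section planes -> per-section circle fits ->
# total-least-squares line through the fitted centers. A closed-form finite
# helical axis from vertex-corresponding poses serves as an independent
# oracle.

#' Plane through three registered landmarks
#'
#' @param p1,p2,p3 non-collinear 3-vectors (mm).
#' @return `plane3` containing the three points.
#' @export
plane_from_landmarks <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- vcross(p2 - p1, p3 - p1)
  if (vnorm(n) / 2 <= 1e-6) {
    stop("landmarks are collinear (triangle area <= 1e-6 mm^2); ",
         "cannot define a section plane", call. = FALSE)
  }
  plane3(p1, n)
}

#' Parallel section planes offset along a direction
#'
#' `count` planes parallel to `base`, at signed offsets centered on it
#' (for the default spacing 1 mm and count 11: -5 ... +5 mm), displaced
#' along `direction`.
#'
#' @param base `plane3`.
#' @param direction offset direction (any nonzero 3-vector).
#' @param spacing offset step (mm), > 0.
#' @param count number of planes, >= 2.
#' @return list of `plane3`.
#' @export
offset_planes <- function(base, direction, spacing = 1, count = 11L) {
  if (count < 2L) {
    stop("count must be >= 2: a single section cannot define an axis",
         call. = FALSE)
  }
  if (!is.finite(spacing) || spacing <= 0) {
    stop("spacing must be > 0", call. = FALSE)
  }
  d <- unitv(direction)
  offs <- (seq_len(count) - (count + 1) / 2) * spacing
  lapply(offs, function(o) plane3(base$point + o * d, base$normal))
}

#' Planar intersection curve of a mesh, nearest a reference point
#'
#' Intersects every triangle with the plane and chains the crossing
#' segments into connected polylines. Of those, the polyline closest to
#' `near` (typically the landmark centroid) is returned, so the concave
#' notch arc is selected rather than the far cortex. An optional seed
#' circle trims the selected polyline to its contiguous portion consistent
#' with that circle, mirroring the manual curve selection of an operator.
#'
#' @param mesh `trimesh`.
#' @param plane `plane3`.
#' @param near 3-vector used to pick among multiple intersection polylines.
#' @param min_points minimum points required on the selected curve.
#' @param seed_circle optional list `(center, radius)`; points with
#'   `| ||p - center|| - radius | > trim_tol * radius` are trimmed away,
#'   keeping the contiguous run containing the point closest to `near`.
#' @param trim_tol relative tolerance of the seed-circle trim.
#' @return object of class `planar_curve`: ordered `points` (n x 3),
#'   `closed` flag and the `plane`.
#' @export
section_curve <- function(mesh, plane, near, min_points = 8L,
                          seed_circle = NULL, trim_tol = 0.25) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- plane_signed_distance(plane, v)
  s[s == 0] <- 1e-12
  pos <- s > 0
  fp <- cbind(pos[f[, 1L]], pos[f[, 2L]], pos[f[, 3L]])
  mixed <- rowSums(fp) %in% c(1L, 2L)
  if (!any(mixed)) stop("plane does not intersect the mesh", call. = FALSE)
  fm <- f[mixed, , drop = FALSE]
  slots <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  seg_keys <- vector("list", 3L)
  key_pts <- new.env(parent = emptyenv())
  seg <- matrix("", nrow(fm), 2L)
  fill <- rep(0L, nrow(fm))
  for (sl in 1:3) {
    a <- fm[, slots[[sl]][1L]]; b <- fm[, slots[[sl]][2L]]
    crossing <- pos[a] != pos[b]
    if (!any(crossing)) next
    ia <- a[crossing]; ib <- b[crossing]
    t <- s[ia] / (s[ia] - s[ib])
    pts <- v[ia, , drop = FALSE] +
      (v[ib, , drop = FALSE] - v[ia, , drop = FALSE]) * t
    keys <- paste(pmin(ia, ib), pmax(ia, ib))
    rows <- which(crossing)
    for (q in seq_along(rows)) {
      r <- rows[q]
      fill[r] <- fill[r] + 1L
      seg[r, fill[r]] <- keys[q]
      assign(keys[q], pts[q, ], envir = key_pts)
    }
  }
  stopifnot(all(fill == 2L))
  # chain segments: each edge key borders at most two crossing faces
  ukeys <- unique(as.vector(seg))
  nb <- split(c(seg[, 2L], seg[, 1L]), c(seg[, 1L], seg[, 2L]))
  visited <- new.env(parent = emptyenv())
  polylines <- list()
  deg <- lengths(nb)[ukeys]
  order_keys <- ukeys[order(deg)]   # start traversal at open ends first
  for (start in order_keys) {
    if (!is.null(visited[[start]])) next
    chain <- start
    visited[[start]] <- TRUE
    prev <- NA_character_
    cur <- start
    closed <- FALSE
    repeat {
      cand <- nb[[cur]]
      if (!is.na(prev)) {
        drop1 <- match(prev, cand)
        if (!is.na(drop1)) cand <- cand[-drop1]
      }
      if (length(chain) > 2L && chain[1L] %in% cand) {
        closed <- TRUE
        break
      }
      cand <- cand[is.na(match(cand, chain))]
      if (length(cand) == 0L) break
      nxt <- cand[1L]
      chain <- c(chain, nxt)
      visited[[nxt]] <- TRUE
      prev <- cur
      cur <- nxt
    }
    pts <- t(vapply(chain, function(k) get(k, envir = key_pts), numeric(3L)))
    polylines[[length(polylines) + 1L]] <- list(points = pts, closed = closed)
  }
  near <- as.numeric(near)
  dmin <- vapply(polylines, function(pl) {
    min(sqrt(rowSums(sweep(pl$points, 2L, near, "-")^2)))
  }, numeric(1L))
  # ignore slivers (e.g. noise-induced micro-loops) when a substantive
  # polyline is available
  sizes <- vapply(polylines, function(pl) nrow(pl$points), integer(1L))
  cand <- which(sizes >= min_points)
  if (length(cand) == 0L) cand <- seq_along(polylines)
  best <- polylines[[cand[which.min(dmin[cand])]]]
  pts <- best$points
  closed <- best$closed
  if (!is.null(seed_circle)) {
    ctr <- as.numeric(seed_circle$center)
    rad <- seed_circle$radius
    dev <- abs(sqrt(rowSums(sweep(pts, 2L, ctr, "-")^2)) - rad)
    ok <- dev <= trim_tol * rad
    anchor <- which.min(rowSums(sweep(pts, 2L, near, "-")^2))
    n <- nrow(pts)
    if (ok[anchor]) {
      idx <- contiguous_ok_run(ok, anchor, closed)
      if (length(idx) < n) {
        pts <- pts[idx, , drop = FALSE]
        closed <- FALSE
      }
    }
  }
  if (nrow(pts) < min_points) {
    stop("selected intersection polyline has fewer than ", min_points,
         " points", call. = FALSE)
  }
  structure(list(points = pts, closed = closed, plane = plane),
            class = "planar_curve")
}

# Maximal contiguous run of TRUE containing `anchor`; circular when
# `closed`. Returns indices in traversal order.
contiguous_ok_run <- function(ok, anchor, closed) {
  n <- length(ok)
  if (closed) {
    lo <- anchor; hi <- anchor; cnt <- 1L
    repeat {
      p <- ((lo - 2L) %% n) + 1L
      if (cnt >= n || !ok[p]) break
      lo <- p; cnt <- cnt + 1L
    }
    repeat {
      p <- (hi %% n) + 1L
      if (cnt >= n || !ok[p] || p == lo) break
      hi <- p; cnt <- cnt + 1L
    }
    if (cnt >= n) return(seq_len(n))
    if (lo <= hi) lo:hi else c(lo:n, 1:hi)
  } else {
    lo <- anchor; hi <- anchor
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    while (hi < n && ok[hi + 1L]) hi <- hi + 1L
    lo:hi
  }
}

# Iterated trimmed circle fit: refit after dropping the points that
# deviate from the current circle. Scrubs stray points (e.g. cortical
# side walls adjacent to the articular arc) that survive the coarse
# seed-circle trim; the polyline selection upstream has already confined
# the curve to the notch neighborhood, so the trim here is by radial
# deviation alone (no contiguity requirement, which a single mid-arc
# outlier would otherwise truncate).
refine_circle_fit <- function(curve, near, k = 3, max_iter = 5L,
                              min_points = 8L) {
  pts <- curve$points
  fit <- fit_circle(curve)
  n0 <- nrow(pts)
  for (it in seq_len(max_iter)) {
    tol <- max(k * fit$rms_residual, 5e-3 * fit$radius)
    dev <- abs(sqrt(rowSums(sweep(pts, 2L, fit$center, "-")^2)) - fit$radius)
    ok <- dev <= tol
    if (sum(ok) < max(min_points, ceiling(0.3 * n0))) break
    if (all(ok)) break
    pts <- pts[ok, , drop = FALSE]
    fit <- fit_circle(structure(list(points = pts, closed = FALSE,
                                     plane = curve$plane),
                                class = "planar_curve"))
  }
  fit
}

#' @export
print.planar_curve <- function(x, ...) {
  cat("planar curve:", nrow(x$points), "points,",
      if (x$closed) "closed" else "open", "\n")
  invisible(x)
}

#' Least-squares circle fit of a planar curve
#'
#' Kasa algebraic fit in the curve's plane followed by one geometric
#' Gauss-Newton refinement of (center, radius). Near-linear arcs (angular
#' extent below `min_arc_deg` as seen from the algebraic center) are
#' rejected as ill-conditioned.
#'
#' @param curve `planar_curve`, or an n x 3 matrix with `plane` supplied.
#' @param plane `plane3` (only when `curve` is a bare matrix).
#' @param min_arc_deg arc-extent guard (deg).
#' @return object of class `circle_fit`: 3-D `center`, `radius`, plane
#'   `normal`, `rms_residual` (mm) and point count `n`.
#' @export
fit_circle <- function(curve, plane = NULL, min_arc_deg = 60) {
  if (inherits(curve, "planar_curve")) {
    pts <- curve$points; plane <- curve$plane
  } else {
    pts <- as_points(curve)
    if (is.null(plane)) stop("plane required for bare point input",
                             call. = FALSE)
  }
  if (nrow(pts) < 8L) stop("circle fit needs >= 8 points", call. = FALSE)
  bb <- plane_basis(plane)
  ctr0 <- colMeans(pts)
  rel <- sweep(pts, 2L, ctr0, "-")
  u <- as.numeric(rel %*% bb$e1)
  v <- as.numeric(rel %*% bb$e2)
  A <- cbind(2 * u, 2 * v, 1)
  rhs <- u^2 + v^2
  sol <- qr.solve(A, rhs)
  cu <- sol[1L]; cv <- sol[2L]
  r <- sqrt(max(sol[3L] + cu^2 + cv^2, .Machine$double.eps))
  ang <- sort(atan2(v - cv, u - cu))
  gaps <- c(diff(ang), 2 * pi - (ang[length(ang)] - ang[1L]))
  extent <- rad2deg(2 * pi - max(gaps))
  if (extent < min_arc_deg) {
    stop("ill-conditioned arc: angular extent ",
         sprintf("%.1f", extent), " deg < ", min_arc_deg, " deg",
         call. = FALSE)
  }
  # one Gauss-Newton step on the geometric distance
  di <- sqrt((u - cu)^2 + (v - cv)^2)
  e <- di - r
  J <- cbind(-(u - cu) / di, -(v - cv) / di, -1)
  step <- tryCatch(solve(crossprod(J), -crossprod(J, e)),
                   error = function(e2) matrix(0, 3L, 1L))
  cu <- cu + step[1L]; cv <- cv + step[2L]; r <- r + step[3L]
  di <- sqrt((u - cu)^2 + (v - cv)^2)
  rms <- sqrt(mean((di - r)^2))
  center <- ctr0 + cu * bb$e1 + cv * bb$e2
  structure(list(center = center, radius = r, normal = plane$normal,
                 rms_residual = rms, n = nrow(pts), arc_extent_deg = extent),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle fit: r = %.3f mm, rms residual %.2e mm (n = %d, arc %.0f deg)\n",
              x$radius, x$rms_residual, x$n, x$arc_extent_deg))
  invisible(x)
}

#' Total-least-squares line through section-circle centers
#'
#' Principal axis of the centered covariance (via SVD); the axis point is
#' the centroid and the residual is the rms perpendicular distance.
#'
#' @param centers n x 3 matrix (n >= 3) of fitted circle centers.
#' @param lateral_dir optional humeral lateral (+X) direction fixing the
#'   sign of the axis; when `NULL` the sign makes the largest-magnitude
#'   component positive.
#' @param min_spread_mm minimum spread (mm) of the centers along the
#'   principal direction.
#' @return object of class `rotation_axis`: `point`, unit `direction`,
#'   `rms_residual`, `frame_index`.
#' @export
fit_axis <- function(centers, lateral_dir = c(1, 0, 0), min_spread_mm = 1) {
  centers <- as_points(centers)
  if (nrow(centers) < 3L) stop("need >= 3 centers", call. = FALSE)
  ctr <- colMeans(centers)
  rel <- sweep(centers, 2L, ctr, "-")
  if (max(sqrt(rowSums(rel^2))) < 1e-9) {
    stop("degenerate center spread: all centers coincide", call. = FALSE)
  }
  sv <- svd(rel)
  dir <- sv$v[, 1L]
  proj <- as.numeric(rel %*% dir)
  if (diff(range(proj)) < min_spread_mm) {
    stop("degenerate center spread: centers span < ", min_spread_mm,
         " mm along the principal direction", call. = FALSE)
  }
  if (!is.null(lateral_dir)) {
    if (sum(dir * lateral_dir) < 0) dir <- -dir
  } else if (dir[which.max(abs(dir))] < 0) {
    dir <- -dir
  }
  rms <- sqrt(mean(pmax(0, rowSums(rel^2) - proj^2)))
  rotation_axis(point = ctr, direction = dir, rms_residual = rms)
}

#' Rotation axis (point + unit direction)
#'
#' @param point point on the axis (mm).
#' @param direction unit 3-vector.
#' @param rms_residual fit residual (mm).
#' @param frame_index frame the axis belongs to.
#' @param ... further fields (diagnostics) stored alongside.
#' @return object of class `rotation_axis`.
#' @export
rotation_axis <- function(point, direction, rms_residual = NA_real_,
                          frame_index = NA_integer_, ...) {
  structure(list(point = as.numeric(point), direction = unitv(direction),
                 rms_residual = rms_residual, frame_index = frame_index, ...),
            class = "rotation_axis")
}

#' @export
print.rotation_axis <- function(x, ...) {
  cat(sprintf(
    "rotation axis: point (%s) mm, direction (%s), rms %.2e mm\n",
    paste(sprintf("%.2f", x$point), collapse = ", "),
    paste(sprintf("%.4f", x$direction), collapse = ", "),
    x$rms_residual))
  invisible(x)
}

#' Estimate the instantaneous rotation axis from one posed ulna
#'
#' Full notch-based construction: the plane through the three registered
#' landmarks is offset along its own normal (the mediolateral direction,
#' since the landmark plane is a notch cross-section) into `offset_count`
#' section planes; each section polyline is trimmed by the circle seeded
#' from the landmarks and fitted with a least-squares circle; the axis is
#' the total-least-squares line through the fitted centers.
#'
#' @param mesh posed ulna `trimesh`.
#' @param landmarks 3 x 3 matrix, rows = registered notch points on the
#'   mesh surface.
#' @param config list of options: `offset_spacing` (mm, default 1),
#'   `offset_count` (default 11), `trim_tol` (default 0.25),
#'   `lateral_dir` (default +X), `min_curve_points` (default 8),
#'   `surface_tol` (mm; default twice the mean edge length).
#' @return `rotation_axis` with a `diagnostics` data.frame (one row per
#'   section: offset, n points, fitted radius, rms residual).
#' @export
estimate_instantaneous_axis <- function(mesh, landmarks, config = list()) {
  cfg <- utils::modifyList(list(offset_spacing = 1, offset_count = 11L,
                                trim_tol = 0.25, lateral_dir = c(1, 0, 0),
                                min_curve_points = 8L, surface_tol = NULL),
                           config)
  landmarks <- as_points(landmarks)
  stopifnot(nrow(landmarks) == 3L)
  tol <- cfg$surface_tol
  if (is.null(tol)) tol <- 2 * mean_edge_length(mesh)
  dmin <- vapply(seq_len(3L), function(i) {
    min(sqrt(rowSums(sweep(mesh$vertices, 2L, landmarks[i, ], "-")^2)))
  }, numeric(1L))
  if (any(dmin > tol)) {
    stop("landmarks are not on the mesh surface (off by ",
         sprintf("%.2f", max(dmin)), " mm)", call. = FALSE)
  }
  base <- plane_from_landmarks(landmarks[1L, ], landmarks[2L, ],
                               landmarks[3L, ])
  seed <- circumcircle3(landmarks[1L, ], landmarks[2L, ], landmarks[3L, ])
  near0 <- colMeans(landmarks)
  planes <- offset_planes(base, base$normal, cfg$offset_spacing,
                          cfg$offset_count)
  centers <- matrix(NA_real_, length(planes), 3L)
  diag_rows <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    pl <- planes[[k]]
    off <- sum((pl$point - base$point) * base$normal)
    res <- tryCatch({
      near_k <- near0 + off * base$normal
      crv <- section_curve(mesh, pl,
                           near = near_k,
                           min_points = cfg$min_curve_points,
                           seed_circle = list(center = seed$center +
                                                off * base$normal,
                                              radius = seed$radius),
                           trim_tol = cfg$trim_tol)
      refine_circle_fit(crv, near = near_k,
                        min_points = cfg$min_curve_points)
    }, error = function(e) {
      stop("section ", k, " (offset ", sprintf("%+.1f", off), " mm): ",
           conditionMessage(e), call. = FALSE)
    })
    centers[k, ] <- res$center
    diag_rows[[k]] <- data.frame(section = k, offset_mm = off, n_points = res$n,
                                 radius_mm = res$radius,
                                 rms_residual_mm = res$rms_residual,
                                 arc_extent_deg = res$arc_extent_deg)
  }
  ax <- fit_axis(centers, lateral_dir = cfg$lateral_dir)
  ax$diagnostics <- do.call(rbind, diag_rows)
  ax$centers <- centers
  ax
}

#' Finite helical (screw displacement) axis between two poses
#'
#' Closed-form least-squares rigid registration (Kabsch) between two
#' vertex-corresponding meshes, then the screw axis of that transform.
#' Serves as an independent oracle for the notch-based estimator.
#'
#' @param meshA,meshB vertex-corresponding `trimesh` poses of one body.
#' @param lateral_dir optional sign convention direction (default +X).
#' @return `rotation_axis` with fields `angle_deg`, `pitch_mm`
#'   (translation along the axis) and `unreliable` (TRUE when the rotation
#'   angle is below 1 degree).
#' @export
helical_axis_oracle <- function(meshA, meshB, lateral_dir = c(1, 0, 0)) {
  A <- meshA$vertices; B <- meshB$vertices
  if (nrow(A) != nrow(B)) {
    stop("meshes are not vertex-corresponding", call. = FALSE)
  }
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca, "-"), sweep(B, 2L, cb, "-"))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t_ <- cb - as.numeric(R %*% ca)
  cosang <- (sum(diag(R)) - 1) / 2
  angle <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  w <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  unreliable <- angle < 1
  if (vnorm(w) < 1e-12) {
    dir <- c(1, 0, 0)
    point <- ca
    pitch <- sum(t_ * dir)
  } else {
    dir <- unitv(w)
    pitch <- sum(t_ * dir)
    t_perp <- t_ - pitch * dir
    M <- diag(3L) - R
    msv <- svd(M)
    dinv <- ifelse(msv$d > 1e-9, 1 / msv$d, 0)
    point <- as.numeric(msv$v %*% (dinv * crossprod(msv$u, t_perp)))
  }
  if (!is.null(lateral_dir) && sum(dir * lateral_dir) < 0) dir <- -dir
  rotation_axis(point = point, direction = dir, rms_residual = NA_real_,
                angle_deg = angle, pitch_mm = pitch, unreliable = unreliable,
                transform = rigid_transform(R, t_))
}

# Shortest distance between a point and the axis line of `true_axis`,
# plus the angle between two axes as lines; convenience for recovery tests.
axis_comparison <- function(est, truth_point, truth_dir) {
  list(angle_deg = line_angle(est$direction, truth_dir),
       line_dist_mm = point_line_distance(matrix(est$point, 1L), truth_point,
                                          truth_dir))
}
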