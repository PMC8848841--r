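# Single-threshold bone segmentation of 3-D image volumes and isosurface
# extraction to a triangle mesh in world (mm) coordinates.

#' 3-D scalar image volume
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing voxel size per axis (mm), length 3, all > 0.
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a rank-3 array",
                                    call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image volume", paste(dim(x$data), collapse = " x "), "voxels, spacing",
      paste(format(x$spacing, digits = 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Thin wrapper around RNifti; returns the intensities with the voxel
#' spacing taken from the header. Orientation handling beyond spacing is
#' deliberately not attempted.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return [image_volume()].
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               spacing = RNifti::pixdim(img)[1:3])
}

#' Single-threshold segmentation
#'
#' @param vol [image_volume()] or 3-D array.
#' @param threshold intensity cutoff; voxels with intensity `>= threshold`
#'   are bone.
#' @return logical array, same shape as the input.
#' @export
threshold_segment <- function(vol, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  data <- if (inherits(vol, "image_volume")) vol$data else vol
  if (length(dim(data)) != 3L) stop("volume must be rank 3", call. = FALSE)
  data >= threshold
}

#' Extract a bone surface mesh from a binary mask
#'
#' Dual-contouring ("naive surface nets") isosurface: one vertex per
#' boundary cell at the centroid of the cell's edge crossings, one quad
#' (two triangles) per sign-crossing voxel edge. The result is a closed,
#' consistently wound surface in world coordinates. Only the largest
#' connected component is returned; the total component count is attached
#' as attribute `n_components`.
#'
#' @param mask logical (or 0/1) 3-D array.
#' @param spacing voxel size (mm), scalar or length 3.
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return `trimesh` with attribute `n_components`.
#' @export
mask_to_mesh <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(mask, "image_volume")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- mask$data
  }
  if (length(dim(mask)) != 3L) stop("mask must be rank 3", call. = FALSE)
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty; nothing to mesh", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d0 <- dim(mask)
  m <- array(FALSE, d0 + 2L)
  m[2:(d0[1L] + 1L), 2:(d0[2L] + 1L), 2:(d0[3L] + 1L)] <- mask
  d <- dim(m)
  dc <- d - 1L                       # dual-cell grid dimensions
  cell_id <- function(i, j, k) (k - 1L) * (dc[1L] * dc[2L]) +
    (j - 1L) * dc[1L] + i
  # world coordinate of padded voxel center (i,j,k)
  vox_w <- function(idx) sweep(sweep(idx - 2, 2L, spacing, "*"), 2L,
                               origin, "+")

  edge_cells <- list(); edge_mid <- list(); edge_inlow <- list()
  for (ax in 1:3) {
    if (ax == 1L) {
      cross <- m[-d[1L], , , drop = FALSE] != m[-1L, , , drop = FALSE]
    } else if (ax == 2L) {
      cross <- m[, -d[2L], , drop = FALSE] != m[, -1L, , drop = FALSE]
    } else {
      cross <- m[, , -d[3L], drop = FALSE] != m[, , -1L, drop = FALSE]
    }
    w <- which(cross)
    if (length(w) == 0L) next
    idx <- arrayInd(w, dim(cross))  # lower voxel of the edge
    i <- idx[, 1L]; j <- idx[, 2L]; k <- idx[, 3L]
    low_in <- m[cbind(i, j, k)]
    mid <- vox_w(idx)
    mid[, ax] <- mid[, ax] + spacing[ax] / 2
    # the 4 dual cells around the edge, in CCW order viewed from +axis
    if (ax == 1L) {
      cells <- cbind(cell_id(i, j - 1L, k - 1L), cell_id(i, j, k - 1L),
                     cell_id(i, j, k), cell_id(i, j - 1L, k))
    } else if (ax == 2L) {
      cells <- cbind(cell_id(i - 1L, j, k - 1L), cell_id(i - 1L, j, k),
                     cell_id(i, j, k), cell_id(i, j, k - 1L))
    } else {
      cells <- cbind(cell_id(i - 1L, j - 1L, k), cell_id(i, j - 1L, k),
                     cell_id(i, j, k), cell_id(i - 1L, j, k))
    }
    edge_cells[[ax]] <- cells
    edge_mid[[ax]] <- mid
    edge_inlow[[ax]] <- low_in
  }
  cells_all <- do.call(rbind, edge_cells)
  mids_all <- do.call(rbind, edge_mid)
  inlow_all <- unlist(edge_inlow)
  # vertex = centroid of the crossing midpoints of each active cell
  flat_cells <- as.vector(cells_all)
  flat_mids <- mids_all[rep(seq_len(nrow(mids_all)), 4L), , drop = FALSE]
  sums <- rowsum(flat_mids, group = flat_cells)
  counts <- as.vector(table(flat_cells))
  uniq <- sort(unique(flat_cells))
  verts <- sums / counts
  vidx <- matrix(match(cells_all, uniq), ncol = 4L)
  rev_ <- !inlow_all
  vidx[rev_, ] <- vidx[rev_, c(4L, 3L, 2L, 1L), drop = FALSE]
  faces <- rbind(vidx[, c(1L, 2L, 3L)], vidx[, c(1L, 3L, 4L)])
  mesh <- trimesh(verts, faces)
  comp <- mesh_face_components(mesh)
  ncomp <- max(comp)
  if (ncomp > 1L) {
    sizes <- tabulate(comp)
    mesh <- subset_mesh_faces(mesh, comp == which.max(sizes))
  }
  attr(mesh, "n_components") <- ncomp
  mesh
}
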