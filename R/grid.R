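#' Volume grid geometry
#'
#' A `volume_grid` describes the sampling geometry shared by all volumes in a
#' study: the voxel dimensions, the voxel size in mm, and the 4x4 voxel-to-world
#' affine. Voxel indices are 0-based with the voxel centre at the integer
#' index (NIfTI centre-of-voxel convention); a world point belongs to voxel
#' `floor(index + 0.5)` along each axis.
#'
#' @param dims integer vector of 3 positive voxel counts.
#' @param voxel_size numeric vector of 3 positive voxel edge lengths (mm).
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims <= 0)) .stopf("dims must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    .stopf("voxel_size must be 3 positive lengths (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4))) .stopf("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) .stopf("affine is not invertible")
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

grids_compatible <- function(a, b, tol = 1e-4) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) <= tol
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' @param grid a [volume_grid()].
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @return n x 3 matrix of coordinates in the other frame.
#' @export
world_to_voxel <- function(grid, points) {
  points <- rbind_points(points)
  inv <- solve(grid$affine)
  out <- cbind(points, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, points) {
  points <- rbind_points(points)
  out <- cbind(points, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  as.matrix(points)
}

# nearest voxel index (0-based, n x 3) of world points
world_to_index <- function(grid, points) {
  v <- world_to_voxel(grid, points)
  floor(v + 0.5)
}

# TRUE where an n x 3 matrix of 0-based indices lies inside the grid
index_in_grid <- function(grid, idx) {
  idx[, 1] >= 0 & idx[, 1] < grid$dims[1] &
  idx[, 2] >= 0 & idx[, 2] < grid$dims[2] &
  idx[, 3] >= 0 & idx[, 3] < grid$dims[3]
}

# 0-based n x 3 index matrix -> 1-based linear index into an array of grid$dims
index_to_linear <- function(grid, idx) {
  1 + idx[, 1] + grid$dims[1] * (idx[, 2] + grid$dims[2] * idx[, 3])
}

# world axis (1=x left-right, 2=y anterior-posterior, 3=z superior-inferior)
# -> the grid index axis most aligned with it, and the sign of the alignment
world_axis_to_grid_axis <- function(grid, world_axis) {
  col <- grid$affine[world_axis, 1:3]
  ax <- which.max(abs(col))
  list(axis = ax, sign = sign(col[ax]))
}

# --- NIfTI helpers -----------------------------------------------------------

grid_from_nifti <- function(img) {
  hdr_dims <- dim(img)[1:3]
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  aff <- matrix(as.numeric(aff), 4, 4)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  volume_grid(hdr_dims, vs, aff)
}

write_nifti_volume <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  extra <- length(dim(arr)) - 3
  RNifti::pixdim(img) <- c(grid$voxel_size, rep(1, max(0, extra)))
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
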