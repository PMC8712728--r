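#' Diffusion-weighted datasets and binary masks
#'
#' `dwi_dataset` bundles a 4-D signal array (x, y, z, volume) with its grid
#' geometry and gradient table; `binary_mask` is a 3-D {0,1} volume on a grid.
#'
#' @param signal 4-D non-negative array; 4th dimension indexes volumes.
#' @param grid a [volume_grid()].
#' @param gradients a [gradient_table()] with one entry per volume.
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, grid, gradients) {
  d <- dim(signal)
  if (length(d) != 4) .stopf("signal must be 4-D, got %d dims", length(d))
  if (!all(d[1:3] == grid$dims)) .stopf("signal dims do not match grid")
  if (d[4] != length(gradients$bvals))
    .stopf("signal has %d volumes but gradient table has %d", d[4],
           length(gradients$bvals))
  if (any(!is.finite(signal)) || any(signal < 0))
    .stopf("signal must be finite and non-negative")
  structure(list(signal = signal, grid = grid, gradients = gradients),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat(sprintf("dwi_dataset: %d x %d x %d voxels, %d volumes\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              dim(x$signal)[4]))
  invisible(x)
}

#' @param values 3-D array; values > 0.5 map to 1, the rest to 0.
#' @rdname dwi_dataset
#' @return `binary_mask` returns an object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid) {
  if (length(dim(values)) != 3) .stopf("mask values must be 3-D")
  if (!all(dim(values) == grid$dims)) .stopf("mask dims do not match grid")
  v <- array(as.integer(values > 0.5), dim = grid$dims)
  structure(list(values = v, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d of %d voxels set\n", sum(x$values),
              prod(x$grid$dims)))
  invisible(x)
}

mask_count <- function(mask) sum(mask$values)

# 0-based n x 3 indices of set voxels
mask_indices <- function(mask) {
  w <- which(mask$values == 1, arr.ind = TRUE)
  unname(w - 1L)
}

#' Read a 4-D diffusion-weighted NIfTI volume
#'
#' @param nifti_path path to a 4-D NIfTI file.
#' @param gradients a [gradient_table()]; its length must equal the number of
#'   volumes in the file.
#' @return A [dwi_dataset()] whose grid is taken from the NIfTI header.
#' @export
read_dwi <- function(nifti_path, gradients) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  if (length(d) != 4)
    .stopf("expected a 4-D NIfTI, got %d-D: %s", length(d), nifti_path)
  if (d[4] != length(gradients$bvals))
    .stopf("NIfTI has %d volumes but gradient table has %d", d[4],
           length(gradients$bvals))
  grid <- grid_from_nifti(img)
  dwi_dataset(array(as.numeric(img), dim = d), grid, gradients)
}

#' Write a [dwi_dataset()] as NIfTI
#' @param dwi a [dwi_dataset()].
#' @param nifti_path output path (.nii or .nii.gz).
#' @export
write_dwi <- function(dwi, nifti_path) {
  write_nifti_volume(dwi$signal, dwi$grid, nifti_path)
}

#' Read a binary mask on a known grid
#'
#' Values > 0.5 are set; no resampling is performed — the mask must already
#' live on `grid` (equal dims, affine within 1e-4).
#'
#' @param nifti_path path to a 3-D NIfTI file.
#' @param grid the [volume_grid()] the mask must match.
#' @return A [binary_mask()].
#' @export
read_mask <- function(nifti_path, grid) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) { img <- array(as.numeric(img), d[1:3]); d <- d[1:3] }
  if (length(d) != 3) .stopf("expected a 3-D NIfTI mask: %s", nifti_path)
  mg <- grid_from_nifti(RNifti::readNifti(nifti_path))
  if (!all(mg$dims == grid$dims))
    .stopf("mask dims %s do not match grid %s", paste(mg$dims, collapse = "x"),
           paste(grid$dims, collapse = "x"))
  if (max(abs(mg$affine - grid$affine)) > 1e-4)
    .stopf("mask affine does not match grid (no resampling is performed)")
  binary_mask(array(as.numeric(img), dim = d), grid)
}

#' Write a [binary_mask()] as NIfTI
#' @param mask a [binary_mask()].
#' @param nifti_path output path.
#' @export
write_mask <- function(mask, nifti_path) {
  write_nifti_volume(array(as.numeric(mask$values), dim = mask$grid$dims),
                     mask$grid, nifti_path)
}
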