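#' Diffusion tensor fitting
#'
#' Per-voxel log-linear ordinary least squares fit of the single tensor model
#' `ln(S/S0) = -b g' D g`, with S0 taken as the mean of all b0 volumes.
#' Fractional anisotropy and the principal eigenvector are derived per voxel
#' for DTI-based tracking. Signals <= 0 are clipped to a small positive floor
#' before the log. Negative eigenvalues produced by noise are kept for the FA
#' formula; the principal direction uses the algebraically largest
#' eigenvalue.
#'
#' @param dwi a [dwi_dataset()] with at least six non-collinear weighted
#'   directions and at least one b0.
#' @param mask a [binary_mask()]; voxels outside are left zero.
#' @return An object of class `tensor_field` with fields `lower` (n_voxel x 6
#'   matrix of Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s, voxel-linear order),
#'   `fa` (vector), `pdir` (n_voxel x 3 matrix), `grid`.
#' @export
fit_tensor <- function(dwi, mask) {
  gtab <- dwi$gradients
  if (!grids_compatible(dwi$grid, mask$grid)) .stopf("mask grid does not match DWI")
  b0 <- is_b0(gtab)
  if (!any(b0)) .stopf("no b0 volume")
  if (sum(!b0) < 6) .stopf("need >= 6 diffusion-weighted volumes")
  g <- gtab$bvecs[!b0, , drop = FALSE]
  b <- gtab$bvals[!b0]
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  if (qr(X)$rank < 6) .stopf("fewer than 6 non-collinear gradient directions")
  dims <- dwi$grid$dims
  nvox <- prod(dims)
  sig <- matrix(dwi$signal, nvox, dim(dwi$signal)[4])
  in_mask <- which(as.vector(mask$values) == 1)
  S0 <- rowMeans(sig[in_mask, b0, drop = FALSE])
  S0 <- pmax(S0, .Machine$double.eps)
  S <- sig[in_mask, !b0, drop = FALSE]
  floor_ <- pmax(1e-6 * S0, .Machine$double.xmin)
  S <- pmax(S, floor_)              # recycles floor_ down columns
  Y <- log(S / S0)
  pinv <- solve(crossprod(X), t(X))
  D <- Y %*% t(pinv)                # n_mask x 6
  lower <- matrix(0, nvox, 6)
  lower[in_mask, ] <- D
  fa <- numeric(nvox)
  pdir <- matrix(0, nvox, 3)
  for (i in seq_along(in_mask)) {
    v <- in_mask[i]
    eg <- tensor_eigen(lower[v, ])
    fa[v] <- fractional_anisotropy(eg$values)
    pdir[v, ] <- eg$vectors[, 1]
  }
  structure(list(lower = lower, fa = fa, pdir = pdir, grid = dwi$grid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %d fitted voxels, FA range [%.3f, %.3f]\n",
              sum(rowSums(abs(x$lower)) > 0), min(x$fa), max(x$fa)))
  invisible(x)
}

# eigen decomposition of a tensor given its 6 unique components,
# eigenvalues sorted descending
tensor_eigen <- function(lower) {
  D <- matrix(c(lower[1], lower[4], lower[5],
                lower[4], lower[2], lower[6],
                lower[5], lower[6], lower[3]), 3, 3)
  eigen(D, symmetric = TRUE)
}

#' Fractional anisotropy of three eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clamped to
#' [0, 1]; returns 0 when all eigenvalues are 0. Negative eigenvalues (from
#' noisy fits) are admitted.
#'
#' @param eigenvalues numeric vector of 3 eigenvalues (mm^2/s).
#' @return FA in [0, 1].
#' @export
fractional_anisotropy <- function(eigenvalues) {
  if (length(eigenvalues) != 3) .stopf("expected 3 eigenvalues")
  ss <- sum(eigenvalues^2)
  if (ss == 0) return(0)
  dev <- eigenvalues - mean(eigenvalues)
  min(1, sqrt(1.5 * sum(dev^2) / ss))
}

#' Export FA and principal-direction maps as NIfTI
#' @param tf a `tensor_field`.
#' @param fa_path,pdir_path optional output paths (NULL to skip).
#' @export
write_tensor_maps <- function(tf, fa_path = NULL, pdir_path = NULL) {
  if (!is.null(fa_path))
    write_nifti_volume(array(tf$fa, tf$grid$dims), tf$grid, fa_path)
  if (!is.null(pdir_path))
    write_nifti_volume(array(tf$pdir, c(tf$grid$dims, 3)), tf$grid, pdir_path)
  invisible(NULL)
}
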