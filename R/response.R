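#' Single-fiber response functions
#'
#' The response function is the canonical diffusion signal profile of a
#' single coherent fiber population, represented by its zonal (m = 0) SH
#' coefficients up to `lmax` for an axis-aligned (z) fiber. It is the
#' deconvolution kernel of CSD. Signals are expressed relative to b0
#' (S/S0), so response amplitudes are dimensionless.
#'
#' @param coef zonal coefficients, one per even degree 0, 2, ..., lmax.
#' @param lmax SH order.
#' @return An object of class `response_function`.
#' @export
response_function <- function(coef, lmax) {
  if (length(coef) != lmax / 2 + 1)
    .stopf("expected %d zonal coefficients for lmax %d", lmax / 2 + 1, lmax)
  if (coef[1] <= 0) .stopf("order-0 response coefficient must be positive")
  structure(list(coef = as.numeric(coef), lmax = as.integer(lmax)),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat("response_function: lmax", x$lmax, "zonal coef",
      paste(signif(x$coef, 4), collapse = " "), "\n")
  invisible(x)
}

# per-coefficient convolution factors: convolving an FOD with the zonal
# kernel multiplies each degree-l coefficient by sqrt(4*pi/(2l+1)) * rho_l
response_conv_factors <- function(resp, lmax = resp$lmax) {
  ls <- sh_degrees(lmax)
  rho <- resp$coef[ls / 2 + 1]
  sqrt(4 * pi / (2 * ls + 1)) * rho
}

# predicted single-fiber signal at unit directions for a z-aligned fiber
response_signal <- function(resp, dirs) {
  dirs <- rbind_points(dirs)
  B <- sh_basis(resp$lmax, dirs)
  as.vector(B[, sh_zonal_cols(resp$lmax)] %*% resp$coef)
}

# fit zonal coefficients to signal samples at unit directions (z-aligned axis)
fit_zonal <- function(dirs, values, lmax) {
  B <- sh_basis(lmax, dirs)[, sh_zonal_cols(lmax), drop = FALSE]
  as.vector(solve(crossprod(B), crossprod(B, values)))
}

#' Response of an axially symmetric diffusion tensor
#'
#' Used to seed the recursive calibration with a deliberately "fat"
#' (low-anisotropy) kernel.
#'
#' @param fa fractional anisotropy of the tensor.
#' @param md mean diffusivity (mm^2/s).
#' @param bval shell b-value (s/mm^2).
#' @param lmax SH order.
#' @return A [response_function()].
#' @export
response_from_tensor <- function(fa = 0.1, md = 0.8e-3, bval = 1000, lmax = 10) {
  # solve lambda_par, lambda_perp from (FA, MD) for (l1, l2, l2)
  f <- function(l1) {
    l2 <- (3 * md - l1) / 2
    l1 - l2 - fa * sqrt(l1^2 + 2 * l2^2)
  }
  l1 <- uniroot(f, c(md, 3 * md - 2e-12))$root
  l2 <- (3 * md - l1) / 2
  dirs <- fibonacci_sphere(256)
  sig <- exp(-bval * (l2 + (l1 - l2) * dirs[, 3]^2))
  response_function(fit_zonal(dirs, sig, lmax), lmax)
}

#' Recursive calibration of the single-fiber response
#'
#' Iterates: (1) deconvolve every candidate voxel with the current response,
#' (2) keep voxels whose second-to-first FOD peak amplitude ratio is below
#' `r_sf` (putative single-fiber voxels), (3) re-estimate the response as
#' the zonal profile of the selected voxels' normalized signals aligned to
#' their principal FOD peak. Stops when the selected set is unchanged or
#' after `max_iter` iterations. The selection step runs the same constrained
#' deconvolution and peak extraction as the tracking pipeline
#' ([csd_deconvolve()] + [extract_peaks()]); the ratio is 0 for voxels with
#' a single accepted peak, so truncation ringing below the peak amplitude
#' threshold does not masquerade as a second fiber population.
#'
#' @param dwi a single-shell [dwi_dataset()].
#' @param mask candidate voxels (white matter).
#' @param lmax SH order of the returned response kernel; kept above the
#'   reported FOD order so deconvolution can run super-resolved (see
#'   [csd_deconvolve()]).
#' @param lmax_fod FOD order used during selection (the pipeline's L_max).
#' @param r_sf single-fiber selection threshold on the peak-2 / peak-1
#'   amplitude ratio.
#' @param max_iter iteration cap.
#' @param init initial [response_function()]; defaults to a fat tensor
#'   response (FA 0.1).
#' @return A [response_function()] with attribute `history`: selected-voxel
#'   count per iteration; attribute `selected`: linear indices of the final
#'   single-fiber voxel set.
#' @export
calibrate_response_recursive <- function(dwi, mask, lmax = 10, lmax_fod = 6,
                                         r_sf = 0.1, max_iter = 10,
                                         init = NULL) {
  gtab <- dwi$gradients
  b0 <- is_b0(gtab)
  bshell <- unique(round(gtab$bvals[!b0]))
  if (length(bshell) != 1) .stopf("recursive calibration needs a single shell")
  if (is.null(init))
    init <- response_from_tensor(fa = 0.1, md = 0.8e-3, bval = bshell, lmax = lmax)
  if (init$lmax != lmax) .stopf("initial response order must equal lmax")

  g <- gtab$bvecs[!b0, , drop = FALSE]
  nc_fod <- sh_ncoef(lmax_fod)
  scale_ <- 1 / fod_delta_peak(lmax_fod)

  sigm <- matrix(dwi$signal, prod(dwi$grid$dims), length(gtab$bvals))
  cand <- which(as.vector(mask$values) == 1)
  S0 <- rowMeans(sigm[cand, b0, drop = FALSE])
  ok <- S0 > 0
  cand <- cand[ok]
  if (!length(cand)) .stopf("response calibration: no candidate voxels")
  S <- sigm[cand, !b0, drop = FALSE] / S0[ok]

  resp <- init
  sel_prev <- integer()
  history <- integer()
  for (it in seq_len(max_iter)) {
    M <- csd_matrices(resp, g, lmax)
    peak1 <- matrix(0, nrow(S), 3)
    ratio <- rep(Inf, nrow(S))
    for (r in seq_len(nrow(S))) {
      f <- scale_ * csd_solve_voxel(S[r, ], M)$f[seq_len(nc_fod)]
      pk <- extract_peaks(f, lmax_fod)
      if (nrow(pk$dirs) == 0) next
      peak1[r, ] <- pk$dirs[1, ]
      ratio[r] <- if (nrow(pk$dirs) == 1) 0
                  else pk$amplitudes[2] / pk$amplitudes[1]
    }
    sel <- which(ratio < r_sf)
    if (!length(sel))
      .stopf("response calibration: no voxels passed single-fiber selection (iteration %d)", it)
    history <- c(history, length(sel))
    # re-estimate: align each selected voxel's gradients to its peak
    rows <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      R <- .rotation_between(peak1[sel[j], ], c(0, 0, 1))
      rows[[j]] <- g %*% t(R)
    }
    dirs_all <- do.call(rbind, rows)
    vals_all <- as.vector(t(S[sel, , drop = FALSE]))
    resp <- response_function(fit_zonal(dirs_all, vals_all, lmax), lmax)
    if (length(sel) == length(sel_prev) && all(sel == sel_prev)) break
    sel_prev <- sel
  }
  attr(resp, "history") <- history
  attr(resp, "selected") <- cand[sel_prev]
  resp
}
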