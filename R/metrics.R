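#' Visitation mask of a tractogram
#'
#' A voxel is set iff at least one streamline point maps into it (voxel
#' centre convention). Streamlines are sampled at no more than half-voxel
#' steps by the trackers, so straight segments cannot skip voxels.
#'
#' @param tg a [tractogram()].
#' @param grid the [volume_grid()] to rasterize on.
#' @return A [binary_mask()].
#' @export
visitation_mask <- function(tg, grid) {
  vals <- array(0, grid$dims)
  for (s in tg$streamlines) {
    idx <- world_to_index(grid, s)
    ok <- index_in_grid(grid, idx)
    if (any(ok)) vals[index_to_linear(grid, idx[ok, , drop = FALSE])] <- 1
  }
  binary_mask(vals, grid)
}

#' Coverage of a reference reconstruction by a candidate
#'
#' The percentage of the reference visitation mask that is also visited by
#' the candidate: `100 * |reference AND candidate| / |reference|`. A value
#' of 90 means 90 percent of the reference bundle's volume is included in
#' the candidate reconstruction.
#'
#' @param reference nonempty reference [binary_mask()] (e.g. the DTI
#'   bundle's visitation mask).
#' @param candidate candidate [binary_mask()] on the same grid.
#' @return list of class `coverage_result`: `percent`, `reference_voxels`,
#'   `intersect_voxels`.
#' @export
coverage <- function(reference, candidate) {
  if (!grids_compatible(reference$grid, candidate$grid))
    .stopf("coverage masks must share one grid")
  nref <- sum(reference$values)
  if (nref == 0) .stopf("coverage is undefined for an empty reference")
  ninter <- sum(reference$values & candidate$values)
  structure(list(percent = 100 * ninter / nref,
                 reference_voxels = nref, intersect_voxels = ninter),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage: %.2f%% (%d of %d reference voxels)\n",
              x$percent, x$intersect_voxels, x$reference_voxels))
  invisible(x)
}

#' Radial extent of a bundle on the motor-cortex arc
#'
#' The motor mask is projected onto the coronal plane (the anterior-
#' posterior axis, identified from the affine, is collapsed). Every
#' projected motor pixel gets a polar angle about the arc centre — a
#' least-squares circle fit of the projected motor pixels, which maps a
#' circular-arc mask uniformly to angle (the fit falls back to the midpoint
#' of the projection's inferior bounding-box edge when the pixels are too
#' collinear to define a circle) — and the angular span of the projection
#' is rescaled to a 90 degree arc, so a bundle covering the whole motor
#' mask scores exactly 90. The arc is divided into 1 degree bins; bins
#' containing at least one projected motor pixel constitute the arc, and
#' the extent is 90 times the fraction of those bins that also contain a
#' bundle-visited motor pixel. For the left hemisphere the lateral
#' direction is mirrored so the sweep runs medial to lateral in both
#' hemispheres.
#'
#' @param bundle_mask visitation mask of the bundle.
#' @param motor_mask nonempty motor-cortex mask on the same grid.
#' @param hemisphere `"left"` or `"right"` (orients the sweep).
#' @return list of class `radial_extent_result`: `degrees` in [0, 90],
#'   `covered_bins` (matrix of arc intervals in degrees), `occupied_bins`,
#'   `n_covered`.
#' @export
radial_extent <- function(bundle_mask, motor_mask, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!grids_compatible(bundle_mask$grid, motor_mask$grid))
    .stopf("radial extent masks must share one grid")
  if (sum(motor_mask$values) == 0) .stopf("motor mask is empty")
  grid <- motor_mask$grid
  ax_lr <- world_axis_to_grid_axis(grid, 1)
  ax_si <- world_axis_to_grid_axis(grid, 3)

  proj <- function(mask_vals) {
    idx <- which(mask_vals == 1, arr.ind = TRUE) - 1
    if (nrow(idx) == 0) return(NULL)
    world <- voxel_to_world(grid, idx)
    unique(cbind(a = world[, 1], b = world[, 3]))
  }
  motor <- proj(motor_mask$values)
  hit <- proj(motor_mask$values & bundle_mask$values)

  a <- motor[, 1]
  if (hemisphere == "left") a <- -a          # lateral sweeps to +a
  b <- motor[, 2]
  ctr <- fit_arc_center(a, b)
  ctr_a <- ctr[1]
  ctr_b <- ctr[2]
  ang <- .rad2deg(atan2(b - ctr_b, a - ctr_a))
  span <- range(ang)
  rescale <- function(x) {
    if (diff(span) < 1e-9) rep(0, length(x))
    else 90 * (x - span[1]) / diff(span)
  }
  bin_of <- function(x) pmin(89L, pmax(0L, as.integer(floor(rescale(x)))))
  occ <- sort(unique(bin_of(ang)))
  covered <- integer(0)
  if (!is.null(hit) && nrow(hit) > 0) {
    ah <- if (hemisphere == "left") -hit[, 1] else hit[, 1]
    angh <- .rad2deg(atan2(hit[, 2] - ctr_b, ah - ctr_a))
    covered <- sort(unique(bin_of(angh)))
    covered <- covered[covered %in% occ]
  }
  width <- 90 / length(occ)
  degrees <- width * length(covered)
  ivals <- if (length(covered))
    cbind(start = width * (match(covered, occ) - 1),
          end = width * match(covered, occ))
  else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  structure(list(degrees = degrees, covered_bins = ivals,
                 occupied_bins = length(occ), n_covered = length(covered)),
            class = "radial_extent_result")
}

#' @export
print.radial_extent_result <- function(x, ...) {
  cat(sprintf("radial extent: %.2f degrees (%d of %d arc bins covered)\n",
              x$degrees, x$n_covered, x$occupied_bins))
  invisible(x)
}

# algebraic (Kasa) least-squares circle fit of 2-D points; falls back to
# the inferior bounding-box edge midpoint for near-collinear pixel sets
fit_arc_center <- function(a, b) {
  fallback <- c((min(a) + max(a)) / 2, min(b))
  if (length(a) < 3) return(fallback)
  X <- cbind(2 * a, 2 * b, 1)
  y <- a^2 + b^2
  G <- crossprod(X)
  if (rcond(G) < 1e-10) return(fallback)
  beta <- solve(G, crossprod(X, y))
  c(beta[1], beta[2])
}

#' Two-sigma outliers of extent differences
#'
#' Flags values whose absolute deviation from the mean exceeds twice the
#' sample standard deviation (strict inequality; values at exactly
#' mean +/- 2 sigma are not flagged).
#'
#' @param differences numeric vector (>= 3 values), e.g. radial-extent
#'   differences between tumor-affected and unaffected hemispheres.
#' @return list: `outliers` (indices), `mean`, `sd`, `threshold`.
#' @export
extent_difference_outliers <- function(differences) {
  if (length(differences) < 3)
    .stopf("need at least 3 values for outlier detection")
  m <- mean(differences)
  s <- stats::sd(differences)
  list(outliers = which(abs(differences - m) > 2 * s),
       mean = m, sd = s, threshold = 2 * s)
}
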