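#' Tracking parameters
#'
#' All propagation thresholds of the deterministic trackers, with defaults
#' matching the clinical tractography setup the toolkit emulates: step size
#' half the smallest voxel dimension, 45 degree angular threshold, FA
#' threshold 0.1 (DTI), FOD peak amplitude threshold 0.08 (CSD/MLFT), five
#' seed points per voxel, and two MLFT levels.
#'
#' @param step_size propagation step (mm); `NULL` = half the smallest voxel
#'   dimension of the grid at tracking time.
#' @param angle_threshold maximum angle between consecutive steps (degrees).
#' @param fa_threshold minimum FA for DTI propagation.
#' @param peak_threshold minimum FOD peak amplitude for CSD/MLFT.
#' @param seeds_per_voxel seed points sampled per seed-mask voxel.
#' @param max_levels MLFT iteration count.
#' @param max_length maximum streamline half-track length (mm).
#' @param rng_seed integer seed for seed sampling.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step_size = NULL, angle_threshold = 45,
                            fa_threshold = 0.1, peak_threshold = 0.08,
                            seeds_per_voxel = 5, max_levels = 2,
                            max_length = 250, rng_seed = 1) {
  if (!is.null(step_size) && step_size <= 0) .stopf("step_size must be > 0")
  if (angle_threshold <= 0 || angle_threshold > 90)
    .stopf("angle_threshold must be in (0, 90]")
  if (seeds_per_voxel < 1) .stopf("seeds_per_voxel must be >= 1")
  if (max_levels < 1) .stopf("max_levels must be >= 1")
  structure(list(step_size = step_size, angle_threshold = angle_threshold,
                 fa_threshold = fa_threshold, peak_threshold = peak_threshold,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 max_levels = as.integer(max_levels), max_length = max_length,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

resolve_step <- function(params, grid) {
  if (!is.null(params$step_size)) params$step_size
  else min(grid$voxel_size) / 2
}

#' Sample seed points in a single-slice seed mask
#'
#' Draws `seeds_per_voxel` points per mask voxel, uniformly within the
#' voxel's in-plane extent; the through-plane coordinate is fixed to the
#' voxel-centre plane so all seeds lie on one slice. The through-plane axis
#' is the grid axis along which the mask occupies a single index (ties
#' resolved toward the last axis).
#'
#' @param seed_mask a nonempty single-slice [binary_mask()].
#' @param seeds_per_voxel points per voxel.
#' @param rng_seed integer seed; identical seeds give identical points.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
sample_seeds <- function(seed_mask, seeds_per_voxel = 5, rng_seed = 1) {
  idx <- mask_indices(seed_mask)
  if (nrow(idx) == 0) .stopf("seed mask is empty")
  nuniq <- apply(idx, 2, function(v) length(unique(v)))
  ax <- which(nuniq == 1)
  through <- if (length(ax)) max(ax) else 3L
  .with_seed(rng_seed, {
    n <- nrow(idx) * seeds_per_voxel
    rep_idx <- idx[rep(seq_len(nrow(idx)), each = seeds_per_voxel), , drop = FALSE]
    jit <- matrix(runif(n * 3, -0.5, 0.5), n, 3)
    jit[, through] <- 0
    voxel_to_world(seed_mask$grid, rep_idx + jit)
  })
}

# --- field interpolation -----------------------------------------------------

# trilinear interpolation of an n_voxel x k matrix field at one world point;
# voxels outside the grid contribute zero
interp_field <- function(field, grid, point) {
  v <- as.vector(world_to_voxel(grid, point))
  i0 <- floor(v)
  fr <- v - i0
  out <- numeric(ncol(field))
  w8 <- numeric(8)
  idx8 <- integer(8)
  n <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0 + c(dx, dy, dz)
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    if (w == 0) next
    if (ii[1] < 0 || ii[2] < 0 || ii[3] < 0 ||
        ii[1] >= grid$dims[1] || ii[2] >= grid$dims[2] || ii[3] >= grid$dims[3])
      next
    n <- n + 1L
    idx8[n] <- 1 + ii[1] + grid$dims[1] * (ii[2] + grid$dims[2] * ii[3])
    w8[n] <- w
  }
  if (n == 0L) return(out)
  if (n == 1L) return(field[idx8[1], ] * w8[1])
  as.vector(crossprod(field[idx8[seq_len(n)], , drop = FALSE], w8[seq_len(n)]))
}

# is the world point inside the mask (nearest-voxel convention)?
point_in_mask <- function(mask, point) {
  idx <- world_to_index(mask$grid, point)
  if (!index_in_grid(mask$grid, idx)) return(FALSE)
  mask$values[idx[1, 1] + 1, idx[1, 2] + 1, idx[1, 3] + 1] == 1
}

# --- propagation engines -----------------------------------------------------

# one half-track: march from `seed` along `dir0` until a termination fires.
# `stepper(point, prev_dir)` returns list(dir = unit vector or NULL,
# reason = reason if NULL). Returns points (excluding the seed), the step
# direction taken AT each visited point (seed first), and the reason.
march <- function(seed, dir0, stepper, tracking_mask, step, max_steps) {
  pts <- matrix(0, max_steps, 3)
  dirs <- matrix(0, max_steps + 1, 3)
  prev <- dir0
  cur <- seed
  n <- 0L
  reason <- "max_length"
  while (n < max_steps) {
    dirs[n + 1L, ] <- prev
    nxt <- cur + step * prev
    if (!point_in_mask(tracking_mask, nxt)) { reason <- "left_mask"; break }
    n <- n + 1L
    pts[n, ] <- nxt
    cur <- nxt
    st <- stepper(cur, prev)
    if (is.null(st$dir)) { reason <- st$reason; n_dirs_end <- TRUE; break }
    prev <- st$dir
  }
  list(points = pts[seq_len(n), , drop = FALSE],
       dirs = dirs[seq_len(n + 1L), , drop = FALSE],
       reason = reason)
}

# join two half-tracks from one seed into a single streamline.
# Returns points (n x 3) and the local segment directions.
join_halves <- function(seed, fwd, bwd) {
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(seed, 1, 3),
               fwd$points)
  pts
}

#' Propagate one streamline with the DTI model
#'
#' Bidirectional Euler integration along the principal eigenvector of the
#' trilinearly interpolated tensor. The eigenvector is recomputed at every
#' interpolated point and sign-aligned to the previous step. Termination:
#' FA below `fa_threshold` (`low_fa`), step-to-step angle above
#' `angle_threshold` (`angle_exceeded`), tracking-mask exit (`left_mask`),
#' or `max_length` per half-track.
#'
#' @param seed world point inside the tracking mask.
#' @param tensors a [fit_tensor()] result.
#' @param tracking_mask propagation domain.
#' @param params a [tracking_params()].
#' @return list with `points` (n x 3 including the seed), `reasons`
#'   (forward/backward termination), or `NULL` if the seed itself fails the
#'   FA threshold.
#' @export
propagate_dti <- function(seed, tensors, tracking_mask, params = tracking_params()) {
  if (!point_in_mask(tracking_mask, seed)) .stopf("seed outside tracking mask")
  grid <- tensors$grid
  step <- resolve_step(params, grid)
  max_steps <- floor(params$max_length / step)
  cos_thr <- cos(.deg2rad(params$angle_threshold))

  eig_at <- function(point) {
    lw <- interp_field(tensors$lower, grid, point)
    if (all(lw == 0)) return(NULL)
    eg <- tensor_eigen(lw)
    fa <- fractional_anisotropy(eg$values)
    list(dir = eg$vectors[, 1], fa = fa)
  }
  e0 <- eig_at(seed)
  if (is.null(e0) || e0$fa < params$fa_threshold) return(NULL)

  stepper <- function(point, prev) {
    e <- eig_at(point)
    if (is.null(e) || e$fa < params$fa_threshold)
      return(list(dir = NULL, reason = "low_fa"))
    d <- e$dir
    if (sum(d * prev) < 0) d <- -d
    if (sum(d * prev) < cos_thr)
      return(list(dir = NULL, reason = "angle_exceeded"))
    list(dir = d)
  }
  fwd <- march(seed, e0$dir, stepper, tracking_mask, step, max_steps)
  bwd <- march(seed, -e0$dir, stepper, tracking_mask, step, max_steps)
  pts <- join_halves(seed, fwd, bwd)
  if (nrow(pts) < 2) return(NULL)
  list(points = pts, reasons = c(forward = fwd$reason, backward = bwd$reason))
}

#' Propagate one streamline with the CSD model
#'
#' At each step, peaks are extracted from the trilinearly interpolated SH
#' coefficients; the peak axis minimizing angular deviation from the
#' previous direction is followed (sign-aligned). Termination: no peak at
#' or above `peak_threshold` (`no_peak`), minimal deviation above
#' `angle_threshold` (`angle_exceeded`), mask exit (`left_mask`), or
#' `max_length`. With `initial_dir = NULL` propagation is bidirectional
#' from the largest peak at the seed; with a given `initial_dir` (MLFT
#' branch seeds) it is unidirectional.
#'
#' @param seed world point inside the tracking mask.
#' @param fods a [csd_deconvolve()] result.
#' @param tracking_mask propagation domain.
#' @param params a [tracking_params()].
#' @param initial_dir unit vector or `NULL`.
#' @return list with `points` (n x 3 including the seed) and `reasons`
#'   (termination per propagation direction); or `NULL` when no acceptable
#'   peak exists at the seed.
#' @export
propagate_csd <- function(seed, fods, tracking_mask, params = tracking_params(),
                          initial_dir = NULL) {
  if (!point_in_mask(tracking_mask, seed)) .stopf("seed outside tracking mask")
  grid <- fods$grid
  step <- resolve_step(params, grid)
  max_steps <- floor(params$max_length / step)
  cos_thr <- cos(.deg2rad(params$angle_threshold))

  peaks_at <- function(point) {
    cf <- interp_field(fods$coeffs, grid, point)
    if (all(cf == 0)) return(NULL)
    # few refinement steps: the 642-direction search grid already localizes
    # peaks to ~4 degrees, ample for the 45-degree deviation rule
    pk <- extract_peaks(cf, fods$lmax,
                        amplitude_threshold = params$peak_threshold,
                        n_refine = 3)
    if (nrow(pk$dirs) == 0) return(NULL)
    pk
  }
  stepper <- function(point, prev) {
    pk <- peaks_at(point)
    if (is.null(pk)) return(list(dir = NULL, reason = "no_peak"))
    dots <- as.vector(pk$dirs %*% prev)
    i <- which.max(abs(dots))
    if (abs(dots[i]) < cos_thr)
      return(list(dir = NULL, reason = "angle_exceeded"))
    list(dir = sign(dots[i]) * pk$dirs[i, ])
  }

  if (is.null(initial_dir)) {
    pk0 <- peaks_at(seed)
    if (is.null(pk0)) return(NULL)
    d0 <- pk0$dirs[1, ]
    fwd <- march(seed, d0, stepper, tracking_mask, step, max_steps)
    bwd <- march(seed, -d0, stepper, tracking_mask, step, max_steps)
    pts <- join_halves(seed, fwd, bwd)
    if (nrow(pts) < 2) return(NULL)
    list(points = pts,
         reasons = c(forward = fwd$reason, backward = bwd$reason))
  } else {
    fwd <- march(seed, .normalize(initial_dir), stepper, tracking_mask, step,
                 max_steps)
    pts <- rbind(matrix(seed, 1, 3), fwd$points)
    if (nrow(pts) < 2) return(NULL)
    list(points = pts, reasons = c(forward = fwd$reason))
  }
}

#' Whole-bundle deterministic tracking with ROI filtering
#'
#' Propagates from all sampled seeds with the chosen model and keeps the
#' streamlines that traverse the region of interest (at least one point
#' inside `roi_mask`), the filtering used for the DTI- and CSD-based
#' baselines.
#'
#' @param algorithm `"dti"` or `"csd"`.
#' @param field a `tensor_field` (DTI) or `fod_field` (CSD).
#' @param seed_mask single-slice seed region.
#' @param tracking_mask propagation domain.
#' @param roi_mask retention filter; `NULL` keeps everything.
#' @param params a [tracking_params()].
#' @return A [tractogram()] with attribute `termination`: table of
#'   termination reasons, and `n_propagated`: streamline count before ROI
#'   filtering.
#' @export
track_bundle <- function(algorithm = c("dti", "csd"), field, seed_mask,
                         tracking_mask, roi_mask = NULL,
                         params = tracking_params()) {
  algorithm <- match.arg(algorithm)
  for (m in list(seed_mask, tracking_mask))
    if (!grids_compatible(m$grid, field$grid)) .stopf("masks must share the field grid")
  seeds <- sample_seeds(seed_mask, params$seeds_per_voxel, params$rng_seed)
  raw <- vector("list", nrow(seeds))
  reasons <- character()
  for (i in seq_len(nrow(seeds))) {
    if (!point_in_mask(tracking_mask, seeds[i, ])) next
    r <- if (algorithm == "dti")
      propagate_dti(seeds[i, ], field, tracking_mask, params)
    else
      propagate_csd(seeds[i, ], field, tracking_mask, params)
    if (is.null(r)) next
    raw[[i]] <- r$points
    reasons <- c(reasons, r$reasons)
  }
  raw <- Filter(Negate(is.null), raw)
  keep <- if (is.null(roi_mask)) raw
          else Filter(function(p) streamline_hits_mask(p, roi_mask), raw)
  if (!length(keep))
    .warnf("no streamlines survived %s tracking/ROI filtering", algorithm)
  structure(tractogram(keep, field$grid),
            termination = table(reasons), n_propagated = length(raw))
}

# does any streamline point fall in a mask voxel?
streamline_hits_mask <- function(points, mask) {
  idx <- world_to_index(mask$grid, points)
  ok <- index_in_grid(mask$grid, idx)
  if (!any(ok)) return(FALSE)
  lin <- index_to_linear(mask$grid, idx[ok, , drop = FALSE])
  any(mask$values[lin] == 1)
}
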