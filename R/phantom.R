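#' Synthetic branching-bundle phantom
#'
#' Generates diffusion-weighted datasets with a corticospinal-tract-like
#' geometry and full ground truth, so trackers and metrics can be exercised
#' without patient data. Two mirrored trunk-plus-branches systems (one per
#' hemisphere) rise from a shared single-slice seed region, emulating CST
#' reconstruction of both hemispheres from one brainstem seed. Each trunk is
#' a small bundle of parallel voxel columns: a central column continues to an
#' apical target patch, and each remaining column feeds one straight branch
#' that leaves the trunk at the branch level under its prescribed angle and
#' runs to a separate target patch. Voxels crossed by two fiber populations
#' carry both directions with occupancy-proportional volume fractions. The
#' per-hemisphere motor mask is a quarter-circle shell in the coronal plane,
#' giving the radial-extent metric a geometrically meaningful ground truth.
#'
#' @param dims grid size in voxels (default 30 x 30 x 30).
#' @param voxel_size voxel edge lengths in mm (default 2, the clinical
#'   protocol emulated throughout).
#' @param trunk_axis unit vector of the trunk direction (default +z).
#' @param branch_angles angles in degrees, in (0, 90], of the fanning
#'   branches measured from the trunk axis; positive values branch laterally
#'   (away from the midline), negative values medially. Default one 40
#'   degree medial and one 70 degree lateral branch per hemisphere.
#' @param branch_level_fraction height fraction(s) in (0, 1) at which the
#'   branches leave the trunk; scalar or one value per branch.
#' @param volume_fractions reserved; per-voxel fractions are derived from
#'   rasterization occupancy.
#' @param lambda_parallel,lambda_perp axial/radial diffusivities (mm^2/s) of
#'   each fiber population; defaults are typical white-matter values.
#' @param iso_diffusivity diffusivity of the isotropic background (mm^2/s).
#' @param S0 baseline (b0) intensity.
#' @param snr signal-to-noise ratio S0/sigma for Rician noise, or `NULL`
#'   for a noise-free phantom.
#' @param rng_seed integer seed driving the noise.
#' @param gradients a [gradient_table()]; default emulates the clinical
#'   protocol of one b0 plus 32 directions at b = 1000 s/mm^2.
#' @return `phantom_spec` returns an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(30, 30, 30), voxel_size = c(2, 2, 2),
                         trunk_axis = c(0, 0, 1),
                         branch_angles = c(-40, 70),
                         branch_level_fraction = 0.6,
                         volume_fractions = NULL,
                         lambda_parallel = 1.7e-3, lambda_perp = 0.2e-3,
                         iso_diffusivity = 1.0e-3,
                         S0 = 1000, snr = 30, rng_seed = 42,
                         gradients = default_gradients()) {
  if (any(abs(branch_angles) <= 0) || any(abs(branch_angles) > 90))
    .stopf("branch angles must lie in (0, 90] degrees in magnitude")
  nb <- length(branch_angles)
  f <- branch_level_fraction
  if (length(f) == 1) f <- rep(f, nb)
  if (nb > 0 && (length(f) != nb || any(f <= 0) || any(f >= 1)))
    .stopf("branch_level_fraction must be in (0,1), scalar or one per branch")
  if (!is.null(snr) && snr <= 0) .stopf("snr must be > 0 or NULL")
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 trunk_axis = .normalize(trunk_axis),
                 branch_angles = branch_angles,
                 branch_level_fraction = f,
                 lambda_parallel = lambda_parallel, lambda_perp = lambda_perp,
                 iso_diffusivity = iso_diffusivity,
                 S0 = S0, snr = snr, rng_seed = as.integer(rng_seed),
                 gradients = gradients),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param n_dirs number of weighted directions.
#' @param bval b-value of the weighted shell (s/mm^2).
#' @export
default_gradients <- function(n_dirs = 32, bval = 1000) {
  gradient_table(c(0, rep(bval, n_dirs)),
                 rbind(c(0, 0, 0), electrostatic_axes(n_dirs)))
}

#' Multi-tensor forward signal model
#'
#' `S(g) = S0 * sum_i f_i * exp(-b g' D_i g)` with axially symmetric tensors
#' `D_i` oriented along `dirs[i, ]`.
#'
#' @param dirs k x 3 matrix of unit fiber directions (0 rows for a purely
#'   isotropic voxel only if `fractions` is empty too).
#' @param fractions k volume fractions summing to 1.
#' @param gradients a [gradient_table()].
#' @param lambda_parallel,lambda_perp diffusivities (mm^2/s).
#' @param S0 baseline intensity.
#' @return numeric vector of per-volume signal values.
#' @export
simulate_signal <- function(dirs, fractions, gradients,
                            lambda_parallel = 1.7e-3, lambda_perp = 0.2e-3,
                            S0 = 1000) {
  dirs <- rbind_points(dirs)
  if (nrow(dirs) == 0 && length(fractions) > 0 && any(fractions != 0))
    .stopf("nonzero fractions with no fiber directions")
  if (length(fractions) != nrow(dirs))
    .stopf("need one fraction per direction")
  if (abs(sum(fractions) - 1) > 1e-8) .stopf("fractions must sum to 1")
  g <- gradients$bvecs
  b <- gradients$bvals
  out <- numeric(length(b))
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    # g' D g = lambda_perp + (lambda_par - lambda_perp) (g . u)^2
    q <- lambda_perp + (lambda_parallel - lambda_perp) * (g %*% u)^2
    out <- out + fractions[i] * exp(-b * as.vector(q))
  }
  S0 * out
}

#' Add Rician noise to a signal
#'
#' Magnitude-MRI noise: `sqrt((s + n1)^2 + n2^2)` with `n1`, `n2` zero-mean
#' Gaussian of standard deviation `sigma`. Deterministic given `rng_seed`.
#'
#' @param signal numeric vector or array of noise-free intensities.
#' @param sigma noise standard deviation (>= 0); 0 returns the input.
#' @param rng_seed integer seed.
#' @return Noisy values, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, rng_seed = 1) {
  if (sigma < 0) .stopf("sigma must be >= 0")
  if (sigma == 0) return(signal)
  .with_seed(rng_seed, {
    n1 <- rnorm(length(signal), 0, sigma)
    n2 <- rnorm(length(signal), 0, sigma)
    out <- sqrt((signal + n1)^2 + n2^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}

# --- geometry ----------------------------------------------------------------

# rasterize a straight voxel-space segment at quarter-voxel sampling;
# returns a table of voxel linear indices with sample counts
rasterize_segment <- function(grid, from, to, step = 0.25) {
  len <- .vnorm(to - from)
  n <- max(2, ceiling(len / step) + 1)
  t_ <- seq(0, 1, length.out = n)
  pts <- cbind(from[1] + t_ * (to[1] - from[1]),
               from[2] + t_ * (to[2] - from[2]),
               from[3] + t_ * (to[3] - from[3]))
  idx <- floor(pts + 0.5)
  if (any(!index_in_grid(grid, idx)))
    .stopf("phantom geometry exits the grid")
  lin <- index_to_linear(grid, idx)
  table(lin)
}

# small cubic patch of voxels centred on a voxel index
patch_indices <- function(grid, center, radius = 1) {
  rng <- function(c_, d) max(0, c_ - radius):min(d - 1, c_ + radius)
  ex <- expand.grid(rng(center[1], grid$dims[1]),
                    rng(center[2], grid$dims[2]),
                    rng(center[3], grid$dims[3]))
  index_to_linear(grid, as.matrix(ex))
}

#' Generate a branching phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `dwi` (a [dwi_dataset()]) and `truth`, where
#'   `truth` holds per-voxel fiber directions (`dirs`: list of k x 3
#'   matrices indexed by voxel linear index; `fractions` alongside), the
#'   masks (`seed_mask`, `target_mask_left`, `target_mask_right`,
#'   `motor_mask_left`, `motor_mask_right`, `tracking_mask`,
#'   `hemisphere_left`, `hemisphere_right`), the branch table
#'   (`branches`: per-branch hemisphere, angle, junction and endpoint voxel,
#'   `reachable_by_csd` flag = angle magnitude <= 45), and bookkeeping
#'   (`seed_plane_world`: world coordinate of the seed slice along the
#'   trunk axis).
#' @export
make_branching_phantom <- function(spec) {
  grid <- volume_grid(spec$dims, spec$voxel_size)
  dims <- grid$dims
  nvox <- prod(dims)
  cx <- (dims[1] - 1) / 2
  cy <- round((dims[2] - 1) / 2)
  z0 <- max(3L, round(dims[3] * 0.15))         # seed slice
  z_top <- dims[3] - 1L - max(3L, round(dims[3] * 0.2))
  nb <- length(spec$branch_angles)

  # per-population accumulation: list of (linear index counts, direction)
  pops <- list()
  add_pop <- function(counts, dir_, hemi) {
    pops[[length(pops) + 1]] <<- list(counts = counts, dir = dir_, hemi = hemi)
  }

  branch_rows <- list()
  target_lin <- list(left = integer(), right = integer())

  for (hemi in c("left", "right")) {
    lat_sign <- if (hemi == "left") -1 else 1    # lateral = away from midline
    base_x <- if (hemi == "left") floor(cx) else ceiling(cx)
    # trunk columns: central (apex) plus one per branch, offset along x
    offs <- c(0, seq_len(nb))                     # column 0 = central
    x_cols <- base_x + lat_sign * (4 + offs)
    # central column: seed slice to apex
    for (yy in cy:(cy + 1)) {
      cnt <- rasterize_segment(grid, c(x_cols[1], yy, z0), c(x_cols[1], yy, z_top))
      add_pop(cnt, spec$trunk_axis, hemi)
    }
    apex_center <- c(x_cols[1], cy, z_top)
    target_lin[[hemi]] <- c(target_lin[[hemi]], patch_indices(grid, apex_center))
    # branch columns
    for (bi in seq_len(nb)) {
      ang <- spec$branch_angles[bi]
      zb <- round(z0 + spec$branch_level_fraction[bi] * (z_top - z0))
      xc <- x_cols[bi + 1]
      for (yy in cy:(cy + 1)) {
        cnt <- rasterize_segment(grid, c(xc, yy, z0), c(xc, yy, zb))
        add_pop(cnt, spec$trunk_axis, hemi)
      }
      # branch direction in the coronal (x-z) plane; sign of `ang` picks
      # medial (-) vs lateral (+)
      s <- sin(.deg2rad(abs(ang))) * (if (ang >= 0) lat_sign else -lat_sign)
      bdir <- .normalize(c(s, 0, cos(.deg2rad(abs(ang)))))
      # length: reach toward the motor shell but stay clear of midline/edges
      max_len <- 8
      if (sign(s) != lat_sign) {                  # medial branch: stop short
        horiz <- abs(xc - cx) - 2.5
        max_len <- min(max_len, horiz / abs(s))
      } else {
        horiz <- if (hemi == "left") xc - 2.5 else (dims[1] - 3.5) - xc
        max_len <- min(max_len, horiz / abs(s))
      }
      from <- c(xc, cy + 0.5, zb)
      to <- from + max_len * bdir
      for (yy in c(-0.5, 0.5)) {
        cnt <- rasterize_segment(grid, from + c(0, yy, 0), to + c(0, yy, 0))
        add_pop(cnt, bdir, hemi)
      }
      endpoint <- floor(to + 0.5)
      target_lin[[hemi]] <- c(target_lin[[hemi]], patch_indices(grid, endpoint))
      branch_rows[[length(branch_rows) + 1]] <- data.frame(
        hemisphere = hemi, angle = ang,
        junction_x = xc, junction_y = cy, junction_z = zb,
        end_x = endpoint[1], end_y = endpoint[2], end_z = endpoint[3],
        reachable_by_csd = abs(ang) <= 45)
    }
  }

  # merge populations into per-voxel direction sets
  dir_tab <- list()     # voxel linear index -> matrix of dirs, counts
  for (p in pops) {
    lin <- as.integer(names(p$counts))
    for (j in seq_along(lin)) {
      key <- as.character(lin[j])
      entry <- dir_tab[[key]]
      cnt <- as.numeric(p$counts[j])
      if (is.null(entry)) {
        dir_tab[[key]] <- list(dirs = matrix(p$dir, 1, 3), counts = cnt)
      } else {
        # same axis (within 1 degree) accumulates; otherwise a new population
        hit <- which(abs(entry$dirs %*% p$dir) > cos(.deg2rad(1)))
        if (length(hit)) {
          entry$counts[hit[1]] <- entry$counts[hit[1]] + cnt
        } else {
          entry$dirs <- rbind(entry$dirs, p$dir)
          entry$counts <- c(entry$counts, cnt)
        }
        dir_tab[[key]] <- entry
      }
    }
  }

  fiber_lin <- as.integer(names(dir_tab))
  tracking <- array(0, dims); tracking[fiber_lin] <- 1

  # masks
  seed_vals <- array(0, dims)
  sl <- fiber_lin[((fiber_lin - 1) %/% (dims[1] * dims[2])) == z0]
  seed_vals[sl] <- 1
  tgt_l <- array(0, dims); tgt_l[intersect(target_lin$left, fiber_lin)] <- 1
  tgt_r <- array(0, dims); tgt_r[intersect(target_lin$right, fiber_lin)] <- 1
  hemi_l <- array(0, dims); hemi_l[seq_len(floor(cx + 0.5)), , ] <- 1
  hemi_r <- array(0, dims); hemi_r[(ceiling(cx + 1.5)):dims[1], , ] <- 1

  motor <- list()
  for (hemi in c("left", "right")) {
    lat_sign <- if (hemi == "left") -1 else 1
    xc <- (if (hemi == "left") floor(cx) else ceiling(cx)) + lat_sign * 4
    f_arc <- if (nb == 0) 0.6 else mean(spec$branch_level_fraction)
    zb <- round(z0 + f_arc * (z_top - z0))
    r <- z_top - zb
    ex <- expand.grid(x = 0:(dims[1] - 1), z = 0:(dims[3] - 1))
    dx <- (ex$x - xc) * lat_sign                 # lateral distance >= 0
    dz <- ex$z - zb
    d <- sqrt(dx^2 + dz^2)
    on_arc <- d >= r - 1 & d <= r + 1 & dz >= 0 & dx >= -0.5
    m <- array(0, dims)
    for (yy in cy:(cy + 1)) {
      lin <- 1 + ex$x[on_arc] + dims[1] * (yy + dims[2] * ex$z[on_arc])
      m[lin] <- 1
    }
    motor[[hemi]] <- binary_mask(m, grid)
  }

  # signal: S0 * F %*% E with per-population attenuation profiles
  gtab <- spec$gradients
  sig <- matrix(0, nvox, length(gtab$bvals))
  iso_att <- exp(-gtab$bvals * spec$iso_diffusivity)
  sig <- matrix(rep(iso_att, each = nvox), nvox)
  for (key in names(dir_tab)) {
    entry <- dir_tab[[key]]
    v <- as.integer(key)
    fr <- entry$counts / sum(entry$counts)
    sig[v, ] <- simulate_signal(entry$dirs, fr, gtab,
                                spec$lambda_parallel, spec$lambda_perp,
                                S0 = 1)
  }
  sig <- spec$S0 * sig
  if (!is.null(spec$snr))
    sig <- add_rician_noise(sig, spec$S0 / spec$snr, spec$rng_seed)
  dwi <- dwi_dataset(array(sig, c(dims, length(gtab$bvals))), grid, gtab)

  fractions <- lapply(dir_tab, function(e) e$counts / sum(e$counts))
  dirs_list <- lapply(dir_tab, function(e) e$dirs)
  names(dirs_list) <- names(dir_tab); names(fractions) <- names(dir_tab)

  truth <- list(
    dirs = dirs_list, fractions = fractions,
    seed_mask = binary_mask(seed_vals, grid),
    target_mask_left = binary_mask(tgt_l, grid),
    target_mask_right = binary_mask(tgt_r, grid),
    motor_mask_left = motor$left, motor_mask_right = motor$right,
    tracking_mask = binary_mask(tracking, grid),
    hemisphere_left = binary_mask(hemi_l, grid),
    hemisphere_right = binary_mask(hemi_r, grid),
    branches = if (length(branch_rows)) do.call(rbind, branch_rows)
               else data.frame(),
    seed_plane_world = voxel_to_world(grid, c(0, 0, z0))[3],
    apex_z = z_top, seed_z = z0)
  list(dwi = dwi, truth = truth)
}

#' Write a generated phantom to a directory
#'
#' Writes `dwi.nii.gz`, `dwi.bval`, `dwi.bvec`, the masks as NIfTI, and a
#' `truth.json` branch table.
#'
#' @param phantom result of [make_branching_phantom()].
#' @param dir output directory (created if missing).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dwi(phantom$dwi, file.path(dir, "dwi.nii.gz"))
  write_gradient_table(phantom$dwi$gradients, file.path(dir, "dwi.bval"),
                       file.path(dir, "dwi.bvec"))
  t_ <- phantom$truth
  masks <- c(seed = "seed_mask", target_L = "target_mask_left",
             target_R = "target_mask_right", motor_L = "motor_mask_left",
             motor_R = "motor_mask_right", tracking = "tracking_mask",
             hemi_L = "hemisphere_left", hemi_R = "hemisphere_right")
  for (nm in names(masks))
    write_mask(t_[[masks[[nm]]]], file.path(dir, paste0(nm, ".nii.gz")))
  jsonlite::write_json(
    list(branches = t_$branches, seed_plane_world = t_$seed_plane_world),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
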