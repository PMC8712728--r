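# synthetic fields for controlled propagation tests ---------------------------

# uniform tensor field with the given axis over an n-voxel box
uniform_tensor_field <- function(dims, axis, lp = 1.7e-3, lt = 0.2e-3) {
  grid <- volume_grid(dims, c(2, 2, 2))
  u <- mlftrack:::.normalize(axis)
  D <- lt * diag(3) + (lp - lt) * (u %o% u)
  lower <- matrix(rep(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                      each = prod(dims)), prod(dims), 6)
  l <- c(lp, lt, lt)
  structure(list(lower = lower,
                 fa = rep(sqrt(1.5 * sum((l - mean(l))^2) / sum(l^2)), prod(dims)),
                 pdir = matrix(rep(u, each = prod(dims)), prod(dims), 3),
                 grid = grid),
            class = "tensor_field")
}

# FOD field with constant coefficients everywhere
uniform_fod_field <- function(dims, coeffs, lmax = 6) {
  grid <- volume_grid(dims, c(2, 2, 2))
  structure(list(coeffs = matrix(rep(coeffs, each = prod(dims)),
                                 prod(dims), length(coeffs)),
                 grid = grid, lmax = lmax),
            class = "fod_field")
}

box_mask <- function(grid) binary_mask(array(1, grid$dims), grid)

test_that("seed sampling is per-voxel, planar and deterministic", {
  grid <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  vals <- array(0, c(10, 10, 10))
  vals[3:7, 4:5, 6] <- 1                       # 10-voxel single-slice mask
  mask <- binary_mask(vals, grid)

  s <- sample_seeds(mask, 5, rng_seed = 2)
  expect_equal(nrow(s), 50)
  # all seeds share the through-plane coordinate (z voxel 5 centre = 10 mm)
  expect_true(all(s[, 3] == 10))
  # each seed lies within its source voxel's in-plane bounds
  vox <- mlftrack:::world_to_voxel(grid, s)
  src <- mlftrack:::mask_indices(mask)[rep(1:10, each = 5), ]
  expect_true(all(abs(vox[, 1] - src[, 1]) <= 0.5 + 1e-9))
  expect_true(all(abs(vox[, 2] - src[, 2]) <= 0.5 + 1e-9))

  expect_identical(s, sample_seeds(mask, 5, rng_seed = 2))
  expect_false(identical(s, sample_seeds(mask, 5, rng_seed = 3)))

  one <- binary_mask(array(c(rep(0, 500), 1, rep(0, 499)), c(10, 10, 10)), grid)
  s1 <- sample_seeds(one, 5, rng_seed = 1)
  expect_equal(nrow(s1), 5)
  expect_equal(length(unique(s1[, 3])), 1L)

  expect_error(sample_seeds(binary_mask(array(0, c(10, 10, 10)), grid), 5),
               "empty")
})

test_that("DTI propagation runs straight, joins halves, and stops at the mask", {
  tf <- uniform_tensor_field(c(20, 5, 5), c(1, 0, 0))
  mask <- box_mask(tf$grid)
  seed <- c(19, 4, 4)                          # mid-box, world mm
  r <- propagate_dti(seed, tf, mask, tracking_params())
  expect_equal(unname(r$reasons), c("left_mask", "left_mask"))
  # spans the box along x, constant y/z
  expect_lt(min(r$points[, 1]), 2)
  expect_gt(max(r$points[, 1]), 37)
  expect_equal(unique(r$points[, 2]), 4)
  # step-length invariant (1 mm = half of the 2 mm voxel)
  d <- sqrt(rowSums(diff(r$points)^2))
  expect_true(all(abs(d - 1) < 1e-6))
})

test_that("DTI termination reasons fire on constructed fields", {
  # low-FA seed: no propagation
  tf <- uniform_tensor_field(c(10, 5, 5), c(1, 0, 0), lp = 1e-3, lt = 1e-3)
  expect_lt(tf$fa[1], 0.1)
  expect_null(propagate_dti(c(9, 4, 4), tf, box_mask(tf$grid)))

  # 60-degree rotation between two half-spaces: angle_exceeded at the wall
  grid <- volume_grid(c(20, 5, 5), c(2, 2, 2))
  u1 <- c(1, 0, 0)
  u2 <- c(cos(pi / 3), sin(pi / 3), 0)
  mk <- function(u) {
    D <- 0.2e-3 * diag(3) + 1.5e-3 * (u %o% u)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }
  lower <- matrix(0, prod(grid$dims), 6)
  xs <- rep(0:19, times = 25)
  lower[xs < 10, ] <- matrix(rep(mk(u1), each = sum(xs < 10)), ncol = 6)
  lower[xs >= 10, ] <- matrix(rep(mk(u2), each = sum(xs >= 10)), ncol = 6)
  tf2 <- structure(list(lower = lower, fa = rep(0.8, prod(grid$dims)),
                        pdir = matrix(0, prod(grid$dims), 3), grid = grid),
                   class = "tensor_field")
  # trilinear interpolation spreads the 60-degree turn over ~1 voxel, so a
  # half-voxel step sees < 45 degrees per step; a step spanning the blend
  # zone exposes the abrupt rotation
  r <- propagate_dti(c(4, 4, 4), tf2, box_mask(grid),
                     tracking_params(step_size = 4, angle_threshold = 45))
  expect_true("angle_exceeded" %in% r$reasons)
  # the streamline never crosses deep into the rotated half
  expect_lt(max(r$points[, 1]), 24)
})

test_that("CSD propagation chooses the least-deviating peak", {
  # two-lobe FOD everywhere: straight-ahead (z) and 70 degrees off; the
  # tracker entering along +z must keep the 0-degree peak
  u70 <- c(sin(70 * pi / 180), 0, cos(70 * pi / 180))
  ff <- uniform_fod_field(c(8, 8, 20), delta_fod(rbind(c(0, 0, 1), u70)))
  mask <- box_mask(ff$grid)
  r <- propagate_csd(c(7, 7, 19), ff, mask, tracking_params(),
                     initial_dir = c(0, 0, 1))
  expect_equal(unname(r$reasons), "left_mask")
  dirs <- diff(r$points)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_true(all(abs(dirs %*% c(0, 0, 1)) > cos(2 * pi / 180)))

  # a field whose best peak deviates ~70 degrees from the incoming
  # direction terminates with angle_exceeded after the initial blind step
  # (scaled so the raw delta's truncation ring stays below the threshold)
  ff70 <- uniform_fod_field(c(8, 8, 20), 0.8 * delta_fod(u70))
  r <- propagate_csd(c(7, 7, 19), ff70, mask, tracking_params(),
                     initial_dir = c(0, 0, 1))
  expect_equal(unname(r$reasons), "angle_exceeded")
  expect_lte(nrow(r$points), 2)

  # sub-threshold FOD: no peak anywhere
  weak <- uniform_fod_field(c(8, 8, 20), delta_fod(c(0, 0, 1)) * 0.05)
  expect_null(propagate_csd(c(7, 7, 19), weak, mask, tracking_params()))
})

test_that("bundle tracking filters by ROI traversal", {
  ph <- fx_phantom_nf()
  tr <- ph$truth
  tg <- fx_csd_left_nf()
  # every surviving streamline touches the ROI
  expect_true(all(vapply(tg$streamlines, function(p)
    mlftrack:::streamline_hits_mask(p, tr$target_mask_left), logical(1))))
  expect_gt(length(tg$streamlines), 0)
  expect_gte(attr(tg, "n_propagated"), length(tg$streamlines))

  # disjoint ROI: empty result with a warning, not an error
  far <- array(0, tr$tracking_mask$grid$dims)
  far[1, 1, 1] <- 1
  expect_warning(
    empty <- track_bundle("csd", fx_fods_nf(), tr$seed_mask, tr$tracking_mask,
                          binary_mask(far, tr$tracking_mask$grid), fx_params()),
    "no streamlines")
  expect_length(empty$streamlines, 0)
})

test_that("emitted streamlines honor the tracking contracts", {
  ph <- fx_phantom_nf()
  tg <- fx_csd_left_nf()
  step <- min(ph$dwi$grid$voxel_size) / 2
  for (s in tg$streamlines) {
    d <- diff(s)
    len <- sqrt(rowSums(d^2))
    expect_true(all(abs(len - step) < 1e-6))
    if (nrow(d) > 1) {
      dn <- d / len
      cosang <- rowSums(dn[-nrow(dn), , drop = FALSE] * dn[-1, , drop = FALSE])
      expect_true(all(acos(pmin(1, pmax(-1, cosang))) <=
                        mlftrack:::.deg2rad(45) + 1e-6))
    }
    # points stay inside the tracking mask dilated by one step
    idx <- mlftrack:::world_to_index(ph$dwi$grid, s)
    expect_true(all(mlftrack:::index_in_grid(ph$dwi$grid, idx)))
  }

  # determinism: identical params and seed give bit-identical tractograms
  tg2 <- track_bundle("csd", fx_fods_nf(), ph$truth$seed_mask,
                      ph$truth$tracking_mask, ph$truth$target_mask_left,
                      fx_params())
  expect_identical(tg$streamlines, tg2$streamlines)
})
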