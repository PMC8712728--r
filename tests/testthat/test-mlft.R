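test_that("MLFT level 1 is exactly the CSD baseline", {
  l1 <- merged_tractogram(fx_mlft_left_nf(), 1)
  csd <- fx_csd_left_nf()
  expect_identical(l1$streamlines, csd$streamlines)
})

test_that("level 2 recovers the 70-degree branch a CSD tracker cannot turn into", {
  ph <- fx_ph70()
  tr <- ph$truth
  expect_false(any(tr$branches$reachable_by_csd))
  lat <- branch_endpoint_mask(tr, "left")

  csd <- fx_csd70_left()
  ml <- fx_mlft70_left()
  expect_equal(n_hits(csd, lat), 0L)

  lvl2 <- ml$levels[[2]]
  expect_gt(length(lvl2), 0)
  l2tg <- merged_tractogram(ml, 2)
  expect_gte(n_hits(l2tg, lat), 1L)

  # every level-2 streamline reaches the target (by construction)
  for (rec in lvl2)
    expect_true(mlftrack:::streamline_hits_mask(rec$points, tr$target_mask_left))
})

test_that("level-2 prefixes retrace their parents verbatim", {
  ph <- fx_ph70()
  # re-run to keep the failed set of level 1 (mlft_track replaces `failed`
  # with the level-2 failures); reconstruct it from the same inputs
  params <- fx_params()
  seeds <- sample_seeds(ph$truth$seed_mask, params$seeds_per_voxel,
                        params$rng_seed)
  failed1 <- list()
  for (i in seq_len(nrow(seeds))) {
    r <- propagate_csd(seeds[i, ], fx_fods70(), ph$truth$tracking_mask, params)
    if (is.null(r)) next
    if (!mlftrack:::streamline_hits_mask(r$points, ph$truth$target_mask_left))
      failed1[[length(failed1) + 1]] <- r$points
  }
  ml <- fx_mlft70_left()
  for (rec in ml$levels[[2]]) {
    parent <- failed1[[rec$parent_id]]
    bi <- rec$branch_index
    expect_equal(rec$points[seq_len(bi), ], parent[seq_len(bi), ],
                 tolerance = 0)
    # the junction angle may exceed the per-step threshold: that is the
    # algorithm's purpose
  }
  # at least one recovered branch turns by more than 45 degrees
  junction_angles <- vapply(ml$levels[[2]], function(rec) {
    bi <- rec$branch_index
    if (bi < 2 || bi >= nrow(rec$points)) return(NA_real_)
    a <- rec$points[bi, ] - rec$points[bi - 1, ]
    b <- rec$points[bi + 1, ] - rec$points[bi, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  }, numeric(1))
  expect_true(any(junction_angles > 45, na.rm = TRUE))
})

test_that("a phantom whose pathways all succeed yields an empty level 2", {
  ph <- make_branching_phantom(phantom_spec(branch_angles = numeric(0),
                                            snr = NULL))
  resp <- calibrate_response_recursive(ph$dwi, ph$truth$tracking_mask)
  fods <- csd_deconvolve(ph$dwi, resp, ph$truth$tracking_mask)
  ml <- mlft_track(fods, ph$truth$seed_mask, ph$truth$target_mask_left,
                   ph$truth$tracking_mask, fx_params())
  # left-hemisphere pathways all reach the apex target; the right-side
  # pathways fail (wrong hemisphere) but carry no unused peaks to branch on
  expect_equal(length(ml$levels[[2]]), 0L)
})

test_that("branch-seed harvesting follows the duplication and exclusion rules", {
  # straight failed pathway along +z through a field with known peaks at
  # its last point; harvesting at the endpoint has one traversal
  # orientation, so the counts match the complement rule directly
  lmax <- 6
  grid <- volume_grid(c(9, 9, 9), c(2, 2, 2))
  u70 <- c(sin(70 * pi / 180), 0, cos(70 * pi / 180))
  v70 <- c(0, sin(70 * pi / 180), cos(70 * pi / 180))
  mk_field <- function(peak_dirs) {
    # scaled so superposed truncation rings stay below the 0.08 threshold
    cf <- 0.4 * delta_fod(peak_dirs)
    structure(list(coeffs = matrix(rep(cf, each = prod(grid$dims)),
                                   prod(grid$dims), length(cf)),
                   grid = grid, lmax = lmax), class = "fod_field")
  }
  # the traversed direction must be the extracted peak itself, as during
  # real propagation (superposed lobes pull the near-z peak slightly off z)
  mk_failed <- function(field) {
    pk <- extract_peaks(field$coeffs[1, ], lmax, n_refine = 3)
    pz <- pk$dirs[which.max(abs(pk$dirs %*% c(0, 0, 1))), ]
    if (pz[3] < 0) pz <- -pz
    start <- c(8, 8, 4)
    pts <- rbind(start, start + pz, start + 2 * pz, start + 3 * pz)
    list(list(points = pts, harvest_from = 4L))   # endpoint only
  }

  # two peaks, one used (near-z): one branch seed along the unused 70-deg peak
  f2 <- mk_field(rbind(c(0, 0, 1), u70))
  seeds <- harvest_branch_seeds(mk_failed(f2), f2, fx_params())
  expect_length(seeds, 1)
  expect_lt(axis_angle(seeds[[1]]$initial_dir, u70), 3)
  expect_gt(sum(seeds[[1]]$initial_dir * c(0, 0, 1)), 0)  # forward-consistent
  expect_equal(seeds[[1]]$parent_prefix_end, 4L)

  # three peaks, one used: the point is duplicated into two branch seeds
  f3 <- mk_field(rbind(c(0, 0, 1), u70, v70))
  seeds <- harvest_branch_seeds(mk_failed(f3), f3, fx_params())
  expect_length(seeds, 2)

  # only the used peak: nothing to harvest
  f1 <- mk_field(matrix(c(0, 0, 1), 1))
  seeds <- harvest_branch_seeds(mk_failed(f1), f1, fx_params())
  expect_length(seeds, 0)
})

test_that("branch concatenation preserves points and validates the junction", {
  parent <- cbind(0, 0, 0:9)              # 10 points
  tail6 <- rbind(parent[5, ],
                 t(sapply(1:5, function(i) parent[5, ] + i * c(1, 0, 0) / sqrt(1))))
  out <- concatenate_branch(parent, 5L, tail6)
  expect_equal(nrow(out), 10L)            # 5 prefix + 5 tail after junction
  expect_equal(out[1:5, ], parent[1:5, ])
  expect_equal(out[6:10, ], tail6[2:6, ])

  # branch at the parent's last point: simple append
  tail2 <- rbind(parent[10, ], parent[10, ] + c(0, 1, 0))
  out <- concatenate_branch(parent, 10L, tail2)
  expect_equal(nrow(out), 11L)

  # branch at the first point: the output is the tail alone
  tail3 <- rbind(parent[1, ], parent[1, ] + c(0, 1, 0), parent[1, ] + c(0, 2, 0))
  out <- concatenate_branch(parent, 1L, tail3)
  expect_equal(out, tail3)

  # junction mismatch is rejected
  bad <- rbind(parent[5, ] + 0.01, parent[5, ] + c(1, 0, 0))
  expect_error(concatenate_branch(parent, 5L, bad), "branch point")
})

test_that("interhemispheric filtering removes midline bridges above the seed plane", {
  grid <- volume_grid(c(20, 8, 20), c(2, 2, 2))
  left <- array(0, grid$dims);  left[1:10, , ] <- 1
  right <- array(0, grid$dims); right[11:20, , ] <- 1
  lm <- binary_mask(left, grid); rm_ <- binary_mask(right, grid)
  seed_plane <- 8    # world mm

  ipsi <- cbind(seq(4, 12, by = 1), 8, seq(20, 28, by = 1))   # stays left
  bridge <- cbind(seq(10, 30, by = 1), 8, 24)                 # crosses above
  stem <- cbind(seq(16, 24, by = 1), 8, 4)                    # crosses below
  tg <- tractogram(list(ipsi, bridge, stem), grid)
  out <- filter_interhemispheric(tg, lm, rm_, seed_plane)
  expect_length(out$streamlines, 2)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_identical(out$streamlines[[1]], ipsi)
  expect_identical(out$streamlines[[2]], stem)

  # overlapping hemisphere masks are rejected
  both <- binary_mask(array(1, grid$dims), grid)
  expect_error(filter_interhemispheric(tg, both, rm_, seed_plane), "overlap")

  # level structure of a multilevel bundle is preserved
  bundle <- structure(list(levels = list(
    list(list(points = ipsi, level = 1L), list(points = bridge, level = 1L)),
    list(list(points = stem, level = 2L))),
    grid = grid), class = "multilevel_bundle")
  fb <- filter_interhemispheric(bundle, lm, rm_, seed_plane)
  expect_length(fb$levels[[1]], 1)
  expect_length(fb$levels[[2]], 1)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
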