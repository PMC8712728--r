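# Memoized expensive fixtures, shared across test files. Everything is
# generated in code at test time; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (!exists(key, envir = .fx, inherits = FALSE))
    assign(key, builder(), envir = .fx)
  get(key, envir = .fx, inherits = FALSE)
}

# default branching phantom under the emulated clinical conditions
fx_phantom <- function() fx("phantom", function() {
  make_branching_phantom(phantom_spec())
})

# noise-free twin for model-recovery oracles
fx_phantom_nf <- function() fx("phantom_nf", function() {
  make_branching_phantom(phantom_spec(snr = NULL))
})

fx_response_nf <- function() fx("response_nf", function() {
  ph <- fx_phantom_nf()
  calibrate_response_recursive(ph$dwi, ph$truth$tracking_mask)
})

fx_fods_nf <- function() fx("fods_nf", function() {
  ph <- fx_phantom_nf()
  csd_deconvolve(ph$dwi, fx_response_nf(), ph$truth$tracking_mask)
})

fx_tensors_nf <- function() fx("tensors_nf", function() {
  ph <- fx_phantom_nf()
  fit_tensor(ph$dwi, ph$truth$tracking_mask)
})

fx_params <- function() tracking_params(rng_seed = 7)

fx_csd_left_nf <- function() fx("csd_left_nf", function() {
  ph <- fx_phantom_nf()
  track_bundle("csd", fx_fods_nf(), ph$truth$seed_mask,
               ph$truth$tracking_mask, ph$truth$target_mask_left, fx_params())
})

fx_mlft_left_nf <- function() fx("mlft_left_nf", function() {
  ph <- fx_phantom_nf()
  mlft_track(fx_fods_nf(), ph$truth$seed_mask, ph$truth$target_mask_left,
             ph$truth$tracking_mask, fx_params())
})

# phantom whose only branch exceeds the angular threshold (70 degrees)
fx_ph70 <- function() fx("ph70", function() {
  make_branching_phantom(phantom_spec(branch_angles = 70))
})

fx_fods70 <- function() fx("fods70", function() {
  ph <- fx_ph70()
  resp <- calibrate_response_recursive(ph$dwi, ph$truth$tracking_mask)
  csd_deconvolve(ph$dwi, resp, ph$truth$tracking_mask)
})

fx_csd70_left <- function() fx("csd70_left", function() {
  ph <- fx_ph70()
  track_bundle("csd", fx_fods70(), ph$truth$seed_mask,
               ph$truth$tracking_mask, ph$truth$target_mask_left, fx_params())
})

fx_mlft70_left <- function() fx("mlft70_left", function() {
  ph <- fx_ph70()
  mlft_track(fx_fods70(), ph$truth$seed_mask, ph$truth$target_mask_left,
             ph$truth$tracking_mask, fx_params())
})

# cubic patch mask around the lateral branch endpoint of a phantom truth
branch_endpoint_mask <- function(truth, hemi = "left") {
  row <- truth$branches[truth$branches$hemisphere == hemi, ][1, ]
  grid <- truth$tracking_mask$grid
  vals <- array(0, grid$dims)
  ctr <- as.numeric(row[c("end_x", "end_y", "end_z")])
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    v <- ctr + c(dx, dy, dz)
    if (all(v >= 0) && all(v < grid$dims)) vals[v[1] + 1, v[2] + 1, v[3] + 1] <- 1
  }
  binary_mask(vals, grid)
}

n_hits <- function(tg, mask) {
  sum(vapply(tg$streamlines,
             function(p) mlftrack:::streamline_hits_mask(p, mask), logical(1)))
}

# angle between two unit vectors as axes, degrees
axis_angle <- function(a, b) acos(min(1, abs(sum(a * b)))) * 180 / pi

# delta-like FOD coefficients with lobes at the given unit directions
delta_fod <- function(dirs, lmax = 6, weights = NULL) {
  dirs <- matrix(dirs, ncol = 3)
  if (is.null(weights)) weights <- rep(1, nrow(dirs))
  cf <- numeric((lmax + 1) * (lmax + 2) / 2)
  for (i in seq_len(nrow(dirs)))
    cf <- cf + weights[i] * as.vector(sh_basis(lmax, dirs[i, ]))
  cf / mlftrack:::fod_delta_peak(lmax)
}
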