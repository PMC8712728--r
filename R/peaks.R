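#' FOD peak extraction
#'
#' Peaks are local maxima of the FOD over the sphere. Candidates are found
#' on a dense icosphere tessellation (antipodally symmetric, so a full
#' sphere search is equivalent to a hemisphere), refined by projected
#' gradient ascent on the SH expansion, collapsed over antipodes, subjected
#' to a minimum pairwise separation, thresholded on amplitude, and returned
#' sorted by descending amplitude.
#'
#' @param coeffs SH coefficient vector of one FOD.
#' @param lmax SH order matching `coeffs`.
#' @param amplitude_threshold minimum FOD amplitude of a reported peak
#'   (absolute units; the tracking default is 0.08).
#' @param max_peaks maximum number of peaks returned.
#' @param min_separation minimum angle between peaks (degrees).
#' @param n_refine gradient-ascent refinement iterations.
#' @param sphere_order icosphere subdivision order of the search grid.
#' @return A list of class `peak_set`: `dirs` (k x 3, k possibly 0),
#'   `amplitudes` (descending).
#' @export
extract_peaks <- function(coeffs, lmax, amplitude_threshold = 0.08,
                          max_peaks = 3, min_separation = 25,
                          n_refine = 8, sphere_order = 3) {
  stopifnot(length(coeffs) == sh_ncoef(lmax))
  empty <- structure(list(dirs = matrix(0, 0, 3), amplitudes = numeric(0)),
                     class = "peak_set")
  if (all(coeffs == 0) || any(!is.finite(coeffs))) return(empty)
  sph <- icosphere(sphere_order)
  B <- sh_basis_cached(lmax, sphere_order)
  a <- as.vector(B %*% coeffs)
  absdot <- .cached(sprintf("absdot_%d", sphere_order),
                    function() abs(tcrossprod(icosphere(sphere_order))))
  sep <- cos(.deg2rad(min_separation))
  # peel candidate maxima with an angular exclusion zone
  cand_idx <- integer()
  avail <- rep(TRUE, length(a))
  for (k in seq_len(max_peaks + 2)) {
    if (!any(avail)) break
    i <- which(avail)[which.max(a[avail])]
    if (a[i] <= 0) break
    cand_idx <- c(cand_idx, i)
    avail <- avail & absdot[, i] < sep
  }
  if (!length(cand_idx)) return(empty)
  dirs <- sph[cand_idx, , drop = FALSE]
  amps <- a[cand_idx]
  ref <- refine_peaks(dirs, coeffs, lmax, n_refine)
  dirs <- ref$dirs; amps <- ref$amps
  # canonical hemisphere representative, dedup, threshold, sort
  flip <- dirs[, 3] < 0 | (dirs[, 3] == 0 & dirs[, 2] < 0) |
          (dirs[, 3] == 0 & dirs[, 2] == 0 & dirs[, 1] < 0)
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  ord <- order(amps, decreasing = TRUE)
  keep_d <- matrix(0, 0, 3); keep_a <- numeric(0)
  for (i in ord) {
    if (amps[i] < amplitude_threshold) next
    if (nrow(keep_d) && any(abs(keep_d %*% dirs[i, ]) > sep)) next
    keep_d <- rbind(keep_d, dirs[i, ])
    keep_a <- c(keep_a, amps[i])
    if (nrow(keep_d) == max_peaks) break
  }
  structure(list(dirs = keep_d, amplitudes = keep_a), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peak(s)\n", nrow(x$dirs)))
  for (i in seq_len(nrow(x$dirs)))
    cat(sprintf("  [%.3f %.3f %.3f] amplitude %.4f\n",
                x$dirs[i, 1], x$dirs[i, 2], x$dirs[i, 3], x$amplitudes[i]))
  invisible(x)
}

# projected gradient ascent on the sphere for several peaks at once; one
# batched SH evaluation per iteration (current points + 4 tangent probes)
refine_peaks <- function(dirs, coeffs, lmax, n_iter = 8, h = 0.01) {
  k <- nrow(dirs)
  if (k == 0 || n_iter == 0) {
    amps <- as.vector(sh_basis(lmax, dirs) %*% coeffs)
    return(list(dirs = dirs, amps = amps))
  }
  best_d <- dirs
  best_a <- rep(-Inf, k)
  step <- 0.08
  for (it in seq_len(n_iter + 1)) {
    u <- matrix(0, k, 3); v <- matrix(0, k, 3)
    for (i in seq_len(k)) {
      d <- dirs[i, ]
      t1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ui <- .normalize(t1 - sum(t1 * d) * d)
      u[i, ] <- ui
      v[i, ] <- c(d[2] * ui[3] - d[3] * ui[2], d[3] * ui[1] - d[1] * ui[3],
                  d[1] * ui[2] - d[2] * ui[1])
    }
    probes <- .normalize_rows(rbind(dirs, dirs + h * u, dirs - h * u,
                                    dirs + h * v, dirs - h * v))
    pa <- as.vector(sh_basis(lmax, probes) %*% coeffs)
    a0 <- pa[1:k]
    upd <- a0 > best_a
    best_a[upd] <- a0[upd]
    best_d[upd, ] <- dirs[upd, , drop = FALSE]
    if (it > n_iter) break
    gu <- (pa[k + 1:k] - pa[2 * k + 1:k]) / (2 * h)
    gv <- (pa[3 * k + 1:k] - pa[4 * k + 1:k]) / (2 * h)
    gn <- sqrt(gu^2 + gv^2)
    gn[gn == 0] <- 1
    dirs <- .normalize_rows(dirs + step * (gu / gn) * u + step * (gv / gn) * v)
    step <- step * 0.55
  }
  list(dirs = best_d, amps = best_a)
}

# exhaustive dense-sphere argmax; the brute-force oracle for peak search
peak_argmax_dense <- function(coeffs, lmax, sphere_order = 5) {
  sph <- icosphere(sphere_order)
  B <- sh_basis_cached(lmax, sphere_order)
  a <- as.vector(B %*% coeffs)
  i <- which.max(a)
  list(dir = sph[i, ], amplitude = a[i])
}
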