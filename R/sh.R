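#' Real symmetric spherical harmonic basis
#'
#' FODs and diffusion signals are antipodally symmetric functions on the
#' sphere, expanded here in the real, even-order SH basis with
#' Descoteaux-style index ordering: degrees l = 0, 2, ..., L_max, and within
#' each degree orders m = -l, ..., l, where m < 0 terms carry sin(|m| phi)
#' and m > 0 terms cos(m phi). The basis is orthonormal on the sphere. The
#' number of coefficients for order `lmax` is `(lmax+1)(lmax+2)/2`.
#'
#' @param lmax even, non-negative SH order.
#' @param dirs n x 3 matrix of unit directions.
#' @return `sh_basis`: an n x ncoef evaluation matrix (row i = basis values
#'   at `dirs[i, ]`).
#' @export
sh_basis <- function(lmax, dirs) {
  if (lmax %% 2 != 0 || lmax < 0) .stopf("lmax must be even and >= 0")
  dirs <- rbind_points(dirs)
  n <- nrow(dirs)
  z <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  s <- sqrt(pmax(0, 1 - z^2))
  # fully normalized associated Legendre S_l^m (Condon-Shortley phase) by
  # stable recurrence, vectorized over points: S[[m+1]] holds S_l^m columns
  S <- vector("list", lmax + 1)
  for (m in 0:lmax) {
    cols <- matrix(0, n, lmax - m + 1)
    smm <- if (m == 0) rep(sqrt(1 / (4 * pi)), n)
           else S[[m]][, 1] * (-sqrt((2 * m + 1) / (2 * m))) * s
    cols[, 1] <- smm
    if (m < lmax) {
      cols[, 2] <- sqrt(2 * m + 3) * z * smm
      if (m + 2 <= lmax) for (l in (m + 2):lmax) {
        al <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        al1 <- sqrt((4 * (l - 1)^2 - 1) / ((l - 1)^2 - m^2))
        cols[, l - m + 1] <- al * (z * cols[, l - m] - cols[, l - m - 1] / al1)
      }
    }
    S[[m + 1]] <- cols
  }
  out <- matrix(0, n, sh_ncoef(lmax))
  col <- 1
  sq2 <- sqrt(2)
  for (l in seq(0, lmax, by = 2)) {
    for (m in -l:l) {
      am <- abs(m)
      base <- S[[am + 1]][, l - am + 1]
      out[, col] <- if (m < 0) sq2 * base * sin(am * phi)
                    else if (m == 0) base
                    else sq2 * base * cos(m * phi)
      col <- col + 1
    }
  }
  out
}

# reference construction of the same basis via pracma's associated Legendre
# (used as an independent cross-check in the test suite)
sh_basis_pracma <- function(lmax, dirs) {
  dirs <- rbind_points(dirs)
  n <- nrow(dirs)
  z <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  out <- matrix(0, n, sh_ncoef(lmax))
  col <- 1
  for (l in seq(0, lmax, by = 2)) {
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, z)
    if (is.null(dim(P))) P <- matrix(P, ncol = 1)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrm * P[am + 1, ]
      out[, col] <- if (m < 0) sqrt(2) * base * sin(am * phi)
                    else if (m == 0) base
                    else sqrt(2) * base * cos(m * phi)
      col <- col + 1
    }
  }
  out
}

#' @rdname sh_basis
#' @return `sh_ncoef`: the number of even-order coefficients.
#' @export
sh_ncoef <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

# degree l of each coefficient, in basis order
sh_degrees <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

# columns holding the zonal (m = 0) terms
sh_zonal_cols <- function(lmax) {
  ls <- seq(0, lmax, by = 2)
  off <- cumsum(c(0, 2 * ls + 1))[seq_along(ls)]
  as.integer(off + ls + 1)
}

# cached basis over a cached tessellation
sh_basis_cached <- function(lmax, sphere_order) {
  .cached(sprintf("shb_%d_%d", lmax, sphere_order),
          function() sh_basis(lmax, icosphere(sphere_order)))
}
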