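#' Sphere tessellations
#'
#' `icosphere(order)` returns the unit vertices of a subdivided icosahedron
#' (12, 42, 162, 642, 2562, 10242 ... vertices for orders 0, 1, 2, ...), the
#' standard quasi-uniform tessellation for FOD sampling and peak search.
#' `fibonacci_sphere(n)` returns n quasi-uniform directions from the
#' Fibonacci (golden-angle) lattice, used for the CSD constraint sphere.
#'
#' @param order subdivision order (non-negative integer).
#' @return n x 3 matrix of unit vectors.
#' @export
icosphere <- function(order = 3) {
  .cached(sprintf("icosphere_%d", order), function() build_icosphere(order))
}

build_icosphere <- function(order) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- .normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (order > 0) for (k in seq_len(order)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    ukey <- unique(ekey)
    mid_of <- match(ekey, ukey)
    ue <- edges[match(ukey, ekey), , drop = FALSE]
    mids <- .normalize_rows((v[ue[, 1], ] + v[ue[, 2], ]) / 2)
    base <- nrow(v)
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- base + mid_of[1:nf]
    m23 <- base + mid_of[nf + 1:nf]
    m13 <- base + mid_of[2 * nf + 1:nf]
    f <- rbind(cbind(f[, 1], m12, m13), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23), cbind(m12, m23, m13))
  }
  attr(v, "faces") <- f
  v
}

#' Quadrature weights for an icosphere tessellation
#'
#' One third of the total area of the triangles incident to each vertex,
#' scaled to sum to 4 pi; suitable for integrating smooth functions sampled
#' at the vertices.
#'
#' @param order subdivision order passed to [icosphere()].
#' @return numeric vector of per-vertex weights summing to 4 pi.
#' @export
icosphere_weights <- function(order = 3) {
  .cached(sprintf("icow_%d", order), function() {
    v <- icosphere(order)
    f <- attr(v, "faces")
    a <- v[f[, 1], ]; b <- v[f[, 2], ]; c_ <- v[f[, 3], ]
    # spherical triangle area via the van Oosterom-Strackee solid angle
    cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    num <- abs(rowSums(a * cr))
    den <- 1 + rowSums(a * b) + rowSums(b * c_) + rowSums(a * c_)
    area <- 2 * atan2(num, den)
    w <- numeric(nrow(v))
    for (j in 1:3) {
      t_ <- tapply(area, f[, j], sum)
      w[as.integer(names(t_))] <- w[as.integer(names(t_))] + t_ / 3
    }
    w * (4 * pi / sum(w))
  })
}

#' Electrostatically optimized gradient axes
#'
#' Minimizes the Coulomb energy of `n` antipodal point pairs on the sphere
#' (Jones-style scheme optimization), the standard design of clinical
#' diffusion gradient tables. Deterministic: the optimization always starts
#' from the same internal seed.
#'
#' @param n number of axes.
#' @param iters gradient-descent iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
electrostatic_axes <- function(n = 32, iters = 1500) {
  .cached(sprintf("esaxes_%d_%d", n, iters), function() {
    x <- .with_seed(7L, .normalize_rows(matrix(rnorm(n * 3), n, 3)))
    lr <- 0.002
    for (it in seq_len(iters)) {
      G <- matrix(0, n, 3)
      for (s in c(1, -1)) {
        for (i in seq_len(n)) {
          d <- sweep(s * x[-i, , drop = FALSE], 2, x[i, ], function(a, b) b - a)
          r2 <- rowSums(d^2)
          G[i, ] <- G[i, ] + colSums(d / r2^1.5)
        }
      }
      x <- .normalize_rows(x + lr * G)
    }
    x
  })
}

#' @param n number of directions.
#' @rdname icosphere
#' @export
fibonacci_sphere <- function(n = 300) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}
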