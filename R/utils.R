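# internal helpers shared across modules

.vnorm <- function(v) sqrt(sum(v * v))

.normalize <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# rows of m normalized to unit length; zero rows left untouched
.normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  nz <- n > 0
  m[nz, ] <- m[nz, , drop = FALSE] / n[nz]
  m
}

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

# angle in degrees between unit vectors, ignoring sign (axis angle, 0..90)
.axis_angle_deg <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  .rad2deg(acos(d))
}

# angle in degrees between unit vectors, signed orientation (0..180)
.vec_angle_deg <- function(a, b) {
  d <- max(-1, min(1, sum(a * b)))
  .rad2deg(acos(d))
}

# rotation matrix mapping unit vector `from` onto unit vector `to`
.rotation_between <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate 180 degrees about any perpendicular axis
    ax <- if (abs(from[1]) < 0.9) .normalize(c(0, -from[3], from[2]))
          else .normalize(c(-from[3], 0, from[1]))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# evaluate an expression with a temporarily fixed RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# package-level cache for tessellations / basis matrices
.cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .cache, inherits = FALSE))
    assign(key, builder(), envir = .cache)
  get(key, envir = .cache, inherits = FALSE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
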