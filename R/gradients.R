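#' Diffusion gradient tables
#'
#' A gradient table pairs each acquired volume with its diffusion weighting
#' (b-value, s/mm^2) and unit gradient direction. Volumes with
#' `b <= b0_threshold` are treated as unweighted b0 references; clinical b0
#' volumes are rarely exactly zero, so the default threshold is 50 s/mm^2.
#'
#' @param bvals numeric vector of b-values (s/mm^2), all non-negative.
#' @param bvecs n x 3 matrix of gradient directions. Directions of weighted
#'   volumes must have unit norm; non-unit vectors are renormalized with a
#'   warning. Zero vectors are only allowed for b0 entries.
#' @param b0_threshold b-values at or below this count as b0 (s/mm^2).
#' @return An object of class `gradient_table` with fields `bvals`, `bvecs`,
#'   `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- rbind_points(bvecs)
  if (nrow(bvecs) != length(bvals))
    .stopf("gradient table mismatch: %d b-values but %d directions",
           length(bvals), nrow(bvecs))
  if (any(bvals < 0)) .stopf("negative b-value in gradient table")
  if (!any(bvals <= b0_threshold))
    .stopf("gradient table has no b0 entry (b <= %g)", b0_threshold)
  norms <- sqrt(rowSums(bvecs^2))
  dwi <- bvals > b0_threshold
  if (any(dwi & norms == 0))
    .stopf("zero gradient direction for a diffusion-weighted volume")
  off <- dwi & abs(norms - 1) > 1e-6
  if (any(off)) {
    .warnf("renormalized %d non-unit gradient direction(s)", sum(off))
    bvecs[off, ] <- bvecs[off, , drop = FALSE] / norms[off]
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs), b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d volumes (%d b0, %d weighted), b max %g s/mm^2\n",
              length(x$bvals), sum(is_b0(x)), sum(!is_b0(x)), max(x$bvals)))
  invisible(x)
}

is_b0 <- function(gtab) gtab$bvals <= gtab$b0_threshold

n_b0 <- function(gtab) sum(is_b0(gtab))
n_dwi <- function(gtab) sum(!is_b0(gtab))

#' Read an FSL-style bval/bvec gradient table
#'
#' The bval file holds one whitespace-separated row of b-values; the bvec
#' file holds three rows (x, y, z components), or the transposed three-column
#' layout.
#'
#' @param bval_path,bvec_path paths to the text files.
#' @param b0_threshold see [gradient_table()].
#' @return A validated [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, b0_threshold = 50) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) .stopf("file not found: %s", p)
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) {
    v <- scan(text = l, quiet = TRUE)
    if (length(v)) v else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  nr <- length(rows)
  if (nr == 3 && length(rows[[1]]) != 3) {
    bvecs <- t(do.call(rbind, rows))
  } else if (nr == 3 && length(rows[[1]]) == 3 && length(bvals) == 3) {
    bvecs <- t(do.call(rbind, rows))   # ambiguous 3x3; FSL row layout assumed
  } else if (all(vapply(rows, length, 1L) == 3)) {
    bvecs <- do.call(rbind, rows)
  } else {
    .stopf("bvec file is neither 3 rows nor 3 columns: %s", bvec_path)
  }
  if (nrow(bvecs) != length(bvals))
    .stopf("bval/bvec count mismatch: %d vs %d", length(bvals), nrow(bvecs))
  gradient_table(bvals, bvecs, b0_threshold)
}

#' Write a gradient table as FSL bval/bvec files
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "), bval_path)
  lines <- apply(t(gtab$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(NULL)
}
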