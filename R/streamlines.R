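#' Tractograms
#'
#' A streamline is an ordered n x 3 matrix of world coordinates (mm); a
#' tractogram is a list of streamlines together with the grid they were
#' tracked on. Streamline coordinates are always stored in world mm
#' (scanner/affine space); voxel space is entered only for interpolation and
#' visitation masks.
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2, finite).
#' @param grid the reference [volume_grid()].
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list(), grid) {
  for (s in streamlines) {
    if (is.null(dim(s)) || ncol(s) != 3 || nrow(s) < 2)
      .stopf("each streamline must be an n x 3 matrix with n >= 2")
    if (any(!is.finite(s))) .stopf("streamline contains non-finite points")
  }
  structure(list(streamlines = streamlines, grid = grid), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, 1L))
  cat(sprintf("tractogram: %d streamlines, %d points\n",
              length(x$streamlines), np))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

# check the fixed-step invariant of a propagated streamline
streamline_step_lengths <- function(s) {
  d <- diff(s)
  sqrt(rowSums(d^2))
}

#' Write a tractogram to MRtrix TCK or TrackVis TRK format
#'
#' Coordinates are written in world mm for TCK and in the TrackVis voxel-mm
#' convention (voxel index + 0.5, scaled by voxel size) for TRK, using the
#' tractogram's grid affine. Both formats round-trip through
#' [read_tractogram()] within 1e-4 mm.
#'
#' @param tg a [tractogram()].
#' @param path output file path.
#' @param format `"tck"` or `"trk"`; default inferred from the file extension.
#' @export
write_tractogram <- function(tg, path, format = c("auto", "tck", "trk")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tck", "trk")) .stopf("unknown tractogram format: .%s", ext)
    format <- ext
  }
  if (format == "tck") write_tck(tg, path) else write_trk(tg, path)
  invisible(path)
}

#' Read a TCK or TRK tractogram
#' @param path input file path.
#' @param grid optional [volume_grid()] to attach; for TRK the header's
#'   vox_to_ras is used for the voxel-mm to world conversion.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, grid = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = read_tck(path, grid),
         trk = read_trk(path, grid),
         .stopf("unknown tractogram format: .%s", ext))
}

# --- MRtrix .tck -------------------------------------------------------------

write_tck <- function(tg, path) {
  n <- length(tg$streamlines)
  hdr_fixed <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", n))
  # the offset line changes its own length; iterate to a fixed point
  offset <- 0
  for (i in 1:5) {
    lines <- c(hdr_fixed, sprintf("file: . %d", offset), "END")
    new_offset <- sum(nchar(lines, type = "bytes")) + length(lines)  # "\n" each
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  for (s in tg$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

read_tck <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) .stopf("truncated TCK header: %s", path)
      if (ch == "\n") break
      line <- paste0(line, ch)
    }
    hdr <- c(hdr, line)
    if (line == "END") break
  }
  if (hdr[1] != "mrtrix tracks") .stopf("not a TCK file: %s", path)
  kv <- hdr[grepl(":", hdr, fixed = TRUE)]
  keys <- sub(":.*", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  dt <- vals[match("datatype", keys)]
  if (!identical(dt, "Float32LE")) .stopf("unsupported TCK datatype: %s", dt)
  offset <- as.integer(sub("^\\S+\\s+", "", vals[match("file", keys)]))
  seek(con, offset)
  raw_n <- file.size(path) - offset
  vals32 <- readBin(con, "numeric", n = raw_n / 4, size = 4, endian = "little")
  m <- matrix(vals32, ncol = 3, byrow = TRUE)
  sep <- is.nan(m[, 1]) | is.infinite(m[, 1])
  streamlines <- list()
  start <- 1
  for (i in which(sep)) {
    if (i > start) streamlines[[length(streamlines) + 1]] <-
        m[start:(i - 1), , drop = FALSE]
    start <- i + 1
  }
  tractogram(streamlines, grid %||% volume_grid(c(1, 1, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- TrackVis .trk -----------------------------------------------------------

# axis-aligned orientation codes of the affine's rotation part, e.g. "RAS"
voxel_order_string <- function(affine) {
  codes <- c("R", "A", "S"); anti <- c("L", "P", "I")
  out <- character(3)
  for (ax in 1:3) {
    col <- affine[1:3, ax]
    w <- which.max(abs(col))
    out[ax] <- if (col[w] >= 0) codes[w] else anti[w]
  }
  paste(out, collapse = "")
}

write_trk <- function(tg, path) {
  grid <- tg$grid
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, what = "numeric")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             con, size = size, endian = "little")
  writeChar("TRACK", con, nchars = 5, eos = NULL); writeBin(raw(1), con)
  wb(grid$dims, 2, "integer")
  wb(grid$voxel_size, 4)
  wb(c(0, 0, 0), 4)                      # origin (unused by convention)
  wb(0, 2, "integer")                    # n_scalars
  writeBin(raw(200), con)                # scalar names
  wb(0, 2, "integer")                    # n_properties
  writeBin(raw(200), con)                # property names
  wb(as.numeric(t(grid$affine)), 4)      # vox_to_ras, row-major
  writeBin(raw(444), con)                # reserved
  vo <- voxel_order_string(grid$affine)
  writeChar(vo, con, nchars = 3, eos = NULL); writeBin(raw(1), con)
  writeBin(raw(4), con)                  # pad2
  wb(c(1, 0, 0, 0, 1, 0), 4)             # image_orientation_patient
  writeBin(raw(2), con)                  # pad1
  writeBin(raw(6), con)                  # invert/swap flags
  wb(length(tg$streamlines), 4, "integer")
  wb(2, 4, "integer")                    # version
  wb(1000, 4, "integer")                 # hdr_size
  for (s in tg$streamlines) {
    vox <- world_to_voxel(grid, s)
    voxmm <- sweep(vox + 0.5, 2, grid$voxel_size, `*`)
    wb(nrow(s), 4, "integer")
    wb(as.numeric(t(voxmm)), 4)
  }
}

read_trk <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rb <- function(n, size, what = "numeric")
    readBin(con, what, n = n, size = size, endian = "little")
  magic <- readChar(con, 5, useBytes = TRUE)
  if (magic != "TRACK") .stopf("not a TRK file: %s", path)
  readBin(con, raw(), 1)
  dims <- rb(3, 2, "integer")
  voxel_size <- rb(3, 4)
  rb(3, 4)                               # origin
  n_scalars <- rb(1, 2, "integer"); readBin(con, raw(), 200)
  n_props <- rb(1, 2, "integer"); readBin(con, raw(), 200)
  vox_to_ras <- matrix(rb(16, 4), 4, 4, byrow = TRUE)
  readBin(con, raw(), 444 + 4 + 4)       # reserved, voxel_order, pad2
  rb(6, 4); readBin(con, raw(), 2 + 6)
  n_count <- rb(1, 4, "integer")
  version <- rb(1, 4, "integer")
  hdr_size <- rb(1, 4, "integer")
  if (hdr_size != 1000) .stopf("unexpected TRK header size %d", hdr_size)
  if (abs(det(vox_to_ras[1:3, 1:3])) < 1e-12)
    vox_to_ras <- diag(c(voxel_size, 1))
  g <- grid %||% volume_grid(pmax(dims, 1), voxel_size, vox_to_ras)
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(np) == 0) break
    pts <- matrix(rb(np * (3 + n_scalars), 4), ncol = 3 + n_scalars,
                  byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) rb(n_props, 4)
    vox <- sweep(pts, 2, voxel_size, `/`) - 0.5
    streamlines[[length(streamlines) + 1]] <- voxel_to_world(g, vox)
  }
  if (n_count > 0 && length(streamlines) != n_count)
    .warnf("TRK header count %d but %d tracks read", n_count, length(streamlines))
  tractogram(streamlines, g)
}
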