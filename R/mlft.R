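#' Multi-level fiber tracking
#'
#' MLFT iteratively improves a bundle reconstruction between a seed and a
#' target region. Level 1 is plain deterministic CSD tracking from the
#' sampled seeds, split into target-reaching pathways (kept) and failed
#' ones. At each subsequent level, every point of every failed pathway is
#' revisited: FOD peaks at that point that were not followed during the
#' parent's traversal (and do not merely retrace it) become new
#' unidirectional branch seeds — a point with m unused peaks is duplicated
#' into m seeds. Branches that reach the target are concatenated with the
#' parent segment from its origin to the branch point and form the next
#' level. Because levels only ever add pathways, the MLFT reconstruction
#' always covers the CSD baseline, and junction angles between parent and
#' branch may exceed the per-step angular threshold — that is the point of
#' the algorithm: high-angulation branches (such as lateral CST fanning)
#' become reachable.
#'
#' @param fods a [csd_deconvolve()] result.
#' @param seed_mask single-slice seed region.
#' @param target_mask pathways must touch this mask to be retained.
#' @param tracking_mask propagation domain.
#' @param params a [tracking_params()]; `max_levels` sets the number of
#'   iterations (2 in the clinical setup emulated here).
#' @return An object of class `multilevel_bundle`: `levels` is a list of
#'   per-level streamline records (each with `points`, `level`, and for
#'   levels >= 2 `parent_id` and `branch_index` into the parent's points),
#'   `failed` the final failed set, `grid`, `params`.
#' @export
mlft_track <- function(fods, seed_mask, target_mask, tracking_mask,
                       params = tracking_params()) {
  for (m in list(seed_mask, target_mask, tracking_mask))
    if (!grids_compatible(m$grid, fods$grid)) .stopf("masks must share the FOD grid")
  if (mask_count(seed_mask) == 0) .stopf("seed mask is empty")
  if (mask_count(target_mask) == 0) .stopf("target mask is empty")

  seeds <- sample_seeds(seed_mask, params$seeds_per_voxel, params$rng_seed)
  level1 <- list()
  failed <- list()
  for (i in seq_len(nrow(seeds))) {
    if (!point_in_mask(tracking_mask, seeds[i, ])) next
    r <- propagate_csd(seeds[i, ], fods, tracking_mask, params)
    if (is.null(r)) next
    rec <- list(points = r$points, level = 1L, reasons = r$reasons)
    if (streamline_hits_mask(r$points, target_mask)) {
      rec$id <- length(level1) + 1L
      level1[[rec$id]] <- rec
    } else {
      failed[[length(failed) + 1L]] <- rec
    }
  }
  levels <- list(level1)

  for (lev in seq_len(params$max_levels)[-1]) {
    if (!length(failed)) { levels[[lev]] <- list(); next }
    seeds_b <- harvest_branch_seeds(failed, fods, params)
    new_level <- list()
    new_failed <- list()
    for (bs in seeds_b) {
      r <- propagate_csd(bs$position, fods, tracking_mask, params,
                         initial_dir = bs$initial_dir)
      if (is.null(r)) next
      parent <- failed[[bs$parent_id]]
      full <- concatenate_branch(parent$points, bs$parent_prefix_end, r$points)
      rec <- list(points = full, level = lev,
                  parent_id = bs$parent_id, branch_index = bs$parent_prefix_end,
                  tail_start = bs$parent_prefix_end,   # first shared point
                  reasons = r$reasons)
      if (streamline_hits_mask(r$points, target_mask)) {
        rec$id <- length(new_level) + 1L
        new_level[[rec$id]] <- rec
      } else {
        # candidate seed source for the next level; harvest only the new tail
        rec$harvest_from <- bs$parent_prefix_end
        new_failed[[length(new_failed) + 1L]] <- rec
      }
    }
    levels[[lev]] <- new_level
    failed <- new_failed
  }

  structure(list(levels = levels, failed = failed, grid = fods$grid,
                 params = params),
            class = "multilevel_bundle")
}

#' @export
print.multilevel_bundle <- function(x, ...) {
  counts <- vapply(x$levels, length, 1L)
  cat(sprintf("multilevel_bundle: %d level(s); streamlines per level: %s\n",
              length(x$levels), paste(counts, collapse = ", ")))
  invisible(x)
}

#' Flatten a multilevel bundle (or one level) into a tractogram
#' @param bundle a [mlft_track()] result.
#' @param level `NULL` for all levels, or a level index.
#' @return A [tractogram()].
#' @export
merged_tractogram <- function(bundle, level = NULL) {
  recs <- if (is.null(level)) unlist(bundle$levels, recursive = FALSE)
          else bundle$levels[[level]]
  tractogram(lapply(recs, `[[`, "points"), bundle$grid)
}

#' Harvest branch seeds from failed pathways
#'
#' For every point of every failed pathway, FOD peaks are extracted at that
#' point; peaks collinear with the locally traversed direction (within 1
#' degree) are "used", and peaks within 10 degrees of the incoming axis are
#' discarded as backtracking. Each remaining peak yields one branch seed
#' whose initial direction is the peak axis signed to continue the local
#' direction of motion. Level-1 pathways are bidirectional, so both
#' traversal orientations are considered; duplicates landing in the same
#' voxel with directions within 5 degrees are merged.
#'
#' @param failed list of failed pathway records (`points`, optionally
#'   `harvest_from` limiting harvesting to the new tail).
#' @param fods the FOD field.
#' @param params a [tracking_params()].
#' @return List of branch seeds: `position`, `initial_dir`, `parent_id`,
#'   `parent_prefix_end` (index of the branch point in the parent).
#' @export
harvest_branch_seeds <- function(failed, fods, params = tracking_params()) {
  used_tol <- cos(.deg2rad(1))
  back_tol <- cos(.deg2rad(10))
  dedup_tol <- cos(.deg2rad(5))
  grid <- fods$grid
  seeds <- list()
  seen <- list()   # voxel linear index -> matrix of accepted directions
  for (pi in seq_along(failed)) {
    pts <- failed[[pi]]$points
    n <- nrow(pts)
    if (n < 2) next
    segs <- diff(pts)
    segs <- segs / sqrt(rowSums(segs^2))
    from <- failed[[pi]]$harvest_from %||% 1L
    for (j in max(1L, from):n) {
      cf <- interp_field(fods$coeffs, grid, pts[j, ])
      if (all(cf == 0)) next
      pk <- extract_peaks(cf, fods$lmax,
                          amplitude_threshold = params$peak_threshold,
                          n_refine = 3)
      if (nrow(pk$dirs) == 0) next
      adj <- rbind(if (j > 1) segs[j - 1, ], if (j < n) segs[j, ])
      for (orient in c(1, -1)) {
        incoming <- if (orient == 1) {
          if (j > 1) segs[j - 1, ] else NULL
        } else {
          if (j < n) -segs[j, ] else NULL
        }
        if (is.null(incoming)) next
        for (q in seq_len(nrow(pk$dirs))) {
          u <- pk$dirs[q, ]
          if (any(abs(adj %*% u) > used_tol)) next           # used peak
          if (abs(sum(incoming * u)) > back_tol) next        # backtracking
          dir_ <- if (sum(incoming * u) >= 0) u else -u
          lin <- index_to_linear(grid, world_to_index(grid, pts[j, ]))
          key <- as.character(lin)
          prev <- seen[[key]]
          if (!is.null(prev) && any(prev %*% dir_ > dedup_tol)) next
          seen[[key]] <- rbind(prev, dir_)
          seeds[[length(seeds) + 1L]] <- list(
            position = pts[j, ], initial_dir = dir_,
            parent_id = pi, parent_prefix_end = j)
        }
      }
    }
  }
  seeds
}

#' Concatenate a branch tail onto its parent prefix
#'
#' @param parent parent streamline points (n x 3).
#' @param branch_point_index index of the branch point within the parent.
#' @param branch_tail branch points (starting at the branch point, within
#'   1e-6 mm).
#' @return Points matrix: parent rows `1..branch_point_index` followed by
#'   the tail without its duplicated first point. The fixed-step invariant
#'   holds within each part but not across the junction.
#' @export
concatenate_branch <- function(parent, branch_point_index, branch_tail) {
  if (branch_point_index < 1 || branch_point_index > nrow(parent))
    .stopf("branch point index out of range")
  if (max(abs(branch_tail[1, ] - parent[branch_point_index, ])) > 1e-6)
    .stopf("branch tail does not start at the parent branch point")
  rbind(parent[seq_len(branch_point_index), , drop = FALSE],
        branch_tail[-1, , drop = FALSE])
}

#' Remove interhemispheric streamlines from a bundle
#'
#' Streamlines that visit both hemisphere masks at points superior to the
#' seed plane are removed (the shared brainstem seed region below the plane
#' is exempt). Level structure is preserved.
#'
#' @param bundle a [mlft_track()] result or a [tractogram()].
#' @param left_mask,right_mask disjoint hemisphere masks.
#' @param seed_plane world coordinate of the seed slice along the superior
#'   axis (mm).
#' @return Object of the same class with offending streamlines removed.
#' @export
filter_interhemispheric <- function(bundle, left_mask, right_mask, seed_plane) {
  ov <- left_mask$values & right_mask$values
  if (any(ov == 1)) .stopf("hemisphere masks overlap")
  # world z is the superior axis on the axis-aligned grids used here
  crosses <- function(pts) {
    above <- (pts[, 3] - seed_plane) * 1 > 1e-6
    if (!any(above)) return(FALSE)
    p <- pts[above, , drop = FALSE]
    streamline_hits_mask(p, left_mask) && streamline_hits_mask(p, right_mask)
  }
  if (inherits(bundle, "tractogram")) {
    keep <- !vapply(bundle$streamlines, crosses, logical(1))
    out <- tractogram(bundle$streamlines[keep], bundle$grid)
    attr(out, "n_removed") <- sum(!keep)
    return(out)
  }
  n_removed <- 0L
  for (lev in seq_along(bundle$levels)) {
    recs <- bundle$levels[[lev]]
    keep <- !vapply(recs, function(r) crosses(r$points), logical(1))
    n_removed <- n_removed + sum(!keep)
    bundle$levels[[lev]] <- recs[keep]
  }
  attr(bundle, "n_removed") <- n_removed
  bundle
}
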