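#' Multiple-threshold segmentation of a stack into 3D objects
#'
#' The core idea of the counting method: no single threshold separates all
#' boutons, but sweeping thresholds from low to high guarantees every
#' bouton is extracted as a separate connected component at least once.
#' For each threshold `t` (percent of the global maximum intensity), voxels
#' with intensity `>= t%` of the maximum are labeled and 3D connected
#' components are extracted (26-neighborhood by default); each object's
#' unweighted voxel centroid (µm) and volume (µm³) are recorded together
#' with the threshold that produced it.
#'
#' @param grid a `VoxelGrid`; must have a positive maximum and should have
#'   passed [check_saturation()].
#' @param thresholds percentages of the global maximum (default 20-90 in
#'   steps of 10).
#' @param connectivity 26 (default) or 6.
#' @return data.frame of `SegmentedObject`s: columns `threshold`, `label`,
#'   `z`, `y`, `x` (centroid, µm), `voxel_count`, `volume` (µm³).
#' @export
multithreshold_segment <- function(grid, thresholds = seq(20, 90, by = 10),
                                   connectivity = 26L) {
  stopifnot(inherits(grid, "VoxelGrid"), connectivity %in% c(6L, 26L))
  img <- grid$data
  mx <- max(img)
  if (mx <= 0) stop("all-zero image: no maximum intensity", call. = FALSE)
  vs <- grid$voxel_size
  vv <- prod(vs)
  res <- lapply(sort(thresholds), function(t) {
    mask <- img >= (t / 100) * mx
    labels <- .cc_label3d(as.logical(mask), dim(img), as.integer(connectivity))
    nlab <- max(labels)
    if (nlab == 0)
      return(NULL)
    st <- .region_stats(as.integer(labels), dim(img), nlab)
    # centroid of voxel centers: 0-based index mean + 0.5, times spacing
    data.frame(threshold = t, label = seq_len(nlab),
               z = (st[, 2] / st[, 1] + 0.5) * vs[1],
               y = (st[, 3] / st[, 1] + 0.5) * vs[2],
               x = (st[, 4] / st[, 1] + 0.5) * vs[3],
               voxel_count = as.integer(st[, 1]),
               volume = st[, 1] * vv)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(threshold = numeric(0), label = integer(0),
                      z = numeric(0), y = numeric(0), x = numeric(0),
                      voxel_count = integer(0), volume = numeric(0))
  rownames(out) <- NULL
  out
}

#' Size-filter segmented objects
#'
#' Objects larger than `vmax` (default 10 µm³) are removed at every
#' threshold: they almost certainly contain several fused boutons. Objects
#' smaller than `vmin` (default 0.05 µm³) are removed only at the lowest
#' threshold, where they are noise artefacts; at higher thresholds genuine
#' boutons legitimately shrink below the limit as the threshold eats into
#' them, so the minimum is not applied there.
#'
#' @param objects data.frame from [multithreshold_segment()].
#' @param vmax maximum object volume (µm³), applied at all thresholds.
#' @param vmin minimum object volume (µm³), applied at `lowest_threshold`
#'   only.
#' @param lowest_threshold the threshold level the minimum applies to;
#'   defaults to the lowest present in `objects`.
#' @return The filtered data.frame.
#' @export
filter_objects <- function(objects, vmax = 10, vmin = 0.05,
                           lowest_threshold = NULL) {
  if (nrow(objects) == 0) return(objects)
  if (is.null(lowest_threshold)) lowest_threshold <- min(objects$threshold)
  keep <- objects$volume <= vmax &
    !(objects$threshold == lowest_threshold & objects$volume < vmin)
  out <- objects[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge object centers across thresholds into boutons
#'
#' Objects extracted at different thresholds but representing the same
#' bouton have nearly coincident centers. Centers closer than
#' `link_distance` (strictly; default 0.8 µm) are linked, within and across
#' thresholds, and boutons are the connected components of the resulting
#' proximity graph (single linkage, so chains merge transitively). Each
#' bouton's center is the arithmetic mean of its member object centroids.
#'
#' @param objects data.frame from [multithreshold_segment()] /
#'   [filter_objects()].
#' @param link_distance merge radius in µm; pairs at exactly this distance
#'   are not linked.
#' @return A `BoutonSet`: list with `centers` (n x 3, z/y/x µm), `members`
#'   (list of member-object data.frames), `link_distance`.
#' @export
merge_centers <- function(objects, link_distance = 0.8) {
  pts <- cbind(objects$z, objects$y, objects$x)
  if (nrow(pts) > 0 && any(!is.finite(pts)))
    stop("centroids must be finite", call. = FALSE)
  comp <- if (nrow(pts) == 0) integer(0)
          else .link_components(pts, link_distance)
  groups <- split(seq_len(nrow(pts)), comp)
  centers <- t(vapply(groups, function(idx)
    colMeans(pts[idx, , drop = FALSE]), numeric(3)))
  if (length(groups) == 0) centers <- matrix(numeric(0), 0, 3)
  colnames(centers) <- c("z", "y", "x")
  rownames(centers) <- NULL
  structure(list(centers = centers,
                 members = lapply(groups, function(idx)
                   objects[idx, , drop = FALSE]),
                 link_distance = link_distance),
            class = "BoutonSet")
}

#' @export
print.BoutonSet <- function(x, ...) {
  cat(sprintf("BoutonSet: %d boutons (link distance %g µm)\n",
              nrow(x$centers), x$link_distance))
  invisible(x)
}

#' Count boutons with centers inside a ROI
#'
#' Counts merged bouton centers lying in the half-open ROI box. Because a
#' merged center summarizes objects that may straddle the ROI face, this
#' reproduces the boundary-biased raw count of both the manual and the
#' automated protocol; the bias is subsequently removed analytically by
#' [correct_boundary()] / [correct_axial_leakage()] rather than
#' geometrically.
#'
#' @param bouton_set a `BoutonSet`.
#' @param roi a [roi_spec()].
#' @return integer raw count `N_raw`.
#' @export
count_in_roi <- function(bouton_set, roi) {
  stopifnot(inherits(bouton_set, "BoutonSet"), inherits(roi, "ROISpec"))
  if (nrow(bouton_set$centers) == 0) return(0L)
  sum(roi_contains(roi, bouton_set$centers))
}

#' Full counting pipeline on a processed stack
#'
#' Runs segmentation, size filtering, center merging, ROI counting and the
#' axial-leakage correction in sequence on an already deconvolved,
#' resampled and z-cropped stack, logging every parameter used.
#'
#' @param grid processed `VoxelGrid`.
#' @param roi a [roi_spec()]; defaults to the full stack extent.
#' @param mask optional binary `VoxelGrid`; when given, only boutons whose
#'   center falls in a nonzero mask voxel are counted (the ROI is then the
#'   mask bounding box unless supplied too).
#' @param thresholds,vmax,vmin,link_distance,connectivity stage parameters,
#'   see the stage functions.
#' @param r_leak axial leaking depth (µm) for the correction.
#' @param check_sat if `TRUE` and the grid has a known full scale, fail on
#'   saturated voxels before segmenting.
#' @return A `CountResult` (see [correct_axial_leakage()]) with the extra
#'   fields `bouton_set`, `objects_total`, `objects_kept` and `params`.
#' @export
count_pipeline <- function(grid, roi = NULL, mask = NULL,
                           thresholds = seq(20, 90, by = 10),
                           vmax = 10, vmin = 0.05, link_distance = 0.8,
                           connectivity = 26L, r_leak = 1.16,
                           check_sat = TRUE) {
  stopifnot(inherits(grid, "VoxelGrid"))
  if (check_sat && !is.null(grid$full_scale)) {
    sat <- check_saturation(grid)
    if (!sat$pass)
      stop(sprintf("stack is saturated (%d voxels at full scale); %s",
                   sat$n_saturated,
                   "the multi-threshold method requires unsaturated images"),
           call. = FALSE)
  }
  if (is.null(roi)) roi <- roi_spec(c(0, 0, 0), grid_extent(grid))
  stopifnot_roi_inside(roi, grid)
  objects <- multithreshold_segment(grid, thresholds, connectivity)
  kept <- filter_objects(objects, vmax = vmax, vmin = vmin)
  boutons <- merge_centers(kept, link_distance)
  if (!is.null(mask)) {
    keep <- mask_lookup(mask, boutons$centers)
    boutons$centers <- boutons$centers[keep, , drop = FALSE]
    boutons$members <- boutons$members[keep]
  }
  n_raw <- count_in_roi(boutons, roi)
  res <- correct_axial_leakage(n_raw, d_roi = roi$size[1], r_leak = r_leak)
  res$roi <- roi
  res$bouton_set <- boutons
  res$objects_total <- nrow(objects)
  res$objects_kept <- nrow(kept)
  res$params <- list(thresholds = thresholds, vmax = vmax, vmin = vmin,
                     link_distance = link_distance,
                     connectivity = connectivity, r_leak = r_leak)
  res
}

# TRUE where centers (n x 3 z/y/x um) fall in a nonzero voxel of mask
mask_lookup <- function(mask, centers) {
  stopifnot(inherits(mask, "VoxelGrid"))
  if (nrow(centers) == 0) return(logical(0))
  d <- dim(mask$data)
  idx <- sweep(centers, 2, mask$voxel_size, `/`)
  idx <- pmin(pmax(floor(idx) + 1, 1), rep(d, each = nrow(centers)))
  mask$data[cbind(idx[, 1], idx[, 2], idx[, 3])] > 0
}

#' Match detected centers to ground-truth centers
#'
#' Greedy nearest-pair assignment: among all truth-detection pairs closer
#' than `tol`, repeatedly accept the closest remaining pair, removing both
#' partners. Reports precision, recall and the matched pairs — the
#' standard scoring of a detector against a known synthetic field.
#'
#' @param truth,detected n x 3 matrices (or data.frames with z, y, x) of
#'   centers in µm.
#' @param tol maximum match distance (µm), default the 0.8 µm merge radius.
#' @return list with `n_truth`, `n_detected`, `n_matched`, `precision`,
#'   `recall`, `pairs` (matched index pairs and their distances).
#' @export
match_centers <- function(truth, detected, tol = 0.8) {
  truth <- as.matrix(as.data.frame(truth)[, c("z", "y", "x")])
  if (is.data.frame(detected)) detected <- centers_zyx(detected)
  detected <- matrix(as.matrix(detected), ncol = 3)
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(n_truth = nt, n_detected = nd, n_matched = 0L,
                precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                pairs = data.frame(truth = integer(0), detected = integer(0),
                                   distance = numeric(0))))
  }
  dmat <- outer(truth[, 1], detected[, 1], `-`)^2 +
    outer(truth[, 2], detected[, 2], `-`)^2 +
    outer(truth[, 3], detected[, 3], `-`)^2
  dmat <- sqrt(dmat)
  dmat[dmat > tol] <- NA
  pairs <- data.frame(truth = integer(0), detected = integer(0),
                      distance = numeric(0))
  while (any(is.finite(dmat))) {
    k <- arrayInd(which.min(dmat), dim(dmat))
    pairs <- rbind(pairs, data.frame(truth = k[1], detected = k[2],
                                     distance = dmat[k[1], k[2]]))
    dmat[k[1], ] <- NA
    dmat[, k[2]] <- NA
  }
  m <- nrow(pairs)
  list(n_truth = nt, n_detected = nd, n_matched = m,
       precision = m / nd, recall = m / nt, pairs = pairs)
}
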