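#' Running-average 3D density map of bouton centers
#'
#' Slides a cubic volume element (default 10 µm side, i.e. 1000 µm³) on a
#' regular grid of step `step` across the bounding box of a binary mask,
#' counts the bouton centers inside each element, and divides by the
#' element volume that overlaps the mask, scaled to #/1000 µm³. Elements
#' whose mask overlap is below 50% are flagged invalid: at the region
#' boundary a raw box count would report spuriously low densities — the
#' very artifact the overlap normalization avoids.
#'
#' Element boxes are half-open and centered on grid nodes; nodes start at
#' half an element side inside the mask bounding box, so with
#' `step = element_side` the elements tile the box without overlap.
#'
#' @param centers a `BoutonSet`, or an n x 3 matrix / data.frame of centers
#'   (z, y, x in µm).
#' @param mask binary `VoxelGrid` (nonzero = inside the region).
#' @param element_side volume-element side in µm (default 10: 1000 µm³).
#' @param step grid step in µm (default 1).
#' @param min_coverage minimal mask-overlap fraction for a valid element.
#' @return A `DensityMap`: list with `values` (3D array, #/1000 µm³, `NA`
#'   where invalid), `counts`, `coverage`, `valid`, `node_z/y/x` (node
#'   center coordinates, µm), `element_side`, `element_volume`, `step`.
#' @export
density_map <- function(centers, mask, element_side = 10, step = 1,
                        min_coverage = 0.5) {
  stopifnot(inherits(mask, "VoxelGrid"), element_side > 0, step > 0)
  if (inherits(centers, "BoutonSet")) centers <- centers$centers
  if (is.data.frame(centers)) centers <- cbind(centers$z, centers$y, centers$x)
  centers <- matrix(as.matrix(centers), ncol = 3)
  if (sum(mask$data > 0) == 0) stop("empty mask", call. = FALSE)
  vs <- mask$voxel_size

  # mask bounding box in µm
  idx <- which(mask$data > 0, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * vs
  hi <- apply(idx, 2, max) * vs
  if (any(hi - lo < element_side))
    stop("volume element does not fit in the mask extent", call. = FALSE)

  half <- element_side / 2
  nodes <- lapply(1:3, function(a) {
    from <- lo[a] + half
    to <- hi[a] - half
    if (to < from) from else seq(from, to, by = step)
  })
  nz <- length(nodes[[1]]); ny <- length(nodes[[2]]); nx <- length(nodes[[3]])

  # summed-area table of the mask for fast box-overlap volumes
  m <- (mask$data > 0) * 1
  sat <- apply(m, c(2, 3), cumsum)                    # along z
  sat <- aperm(apply(sat, c(1, 3), cumsum), c(2, 1, 3))  # along y
  sat <- aperm(apply(sat, c(1, 2), cumsum), c(2, 3, 1))  # along x
  d <- dim(m)
  box_sum <- function(lo_i, hi_i) {
    # sum of m over voxel index ranges (lo_i, hi_i], 0-based bounds
    f <- function(z, y, x) {
      if (z < 1 || y < 1 || x < 1) return(0)
      sat[min(z, d[1]), min(y, d[2]), min(x, d[3])]
    }
    f(hi_i[1], hi_i[2], hi_i[3]) - f(lo_i[1], hi_i[2], hi_i[3]) -
      f(hi_i[1], lo_i[2], hi_i[3]) - f(hi_i[1], hi_i[2], lo_i[3]) +
      f(lo_i[1], lo_i[2], hi_i[3]) + f(lo_i[1], hi_i[2], lo_i[3]) +
      f(hi_i[1], lo_i[2], lo_i[3]) - f(lo_i[1], lo_i[2], lo_i[3])
  }

  counts <- array(0L, c(nz, ny, nx))
  coverage <- array(0, c(nz, ny, nx))
  element_volume <- element_side^3
  vvox <- prod(vs)
  for (k in seq_len(nx)) for (j in seq_len(ny)) for (i in seq_len(nz)) {
    ctr <- c(nodes[[1]][i], nodes[[2]][j], nodes[[3]][k])
    blo <- ctr - half
    bhi <- ctr + half
    if (nrow(centers) > 0) {
      counts[i, j, k] <- sum(centers[, 1] >= blo[1] & centers[, 1] < bhi[1] &
                             centers[, 2] >= blo[2] & centers[, 2] < bhi[2] &
                             centers[, 3] >= blo[3] & centers[, 3] < bhi[3])
    }
    lo_i <- pmax(round(blo / vs), 0)
    hi_i <- pmin(round(bhi / vs), d)
    mask_vol <- if (all(hi_i > lo_i)) box_sum(lo_i, hi_i) * vvox else 0
    coverage[i, j, k] <- mask_vol / element_volume
  }
  valid <- coverage >= min_coverage
  values <- ifelse(valid, 1000 * counts / (coverage * element_volume), NA_real_)
  structure(list(values = array(values, dim(counts)), counts = counts,
                 coverage = coverage, valid = valid,
                 node_z = nodes[[1]], node_y = nodes[[2]], node_x = nodes[[3]],
                 element_side = element_side, element_volume = element_volume,
                 step = step),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf("DensityMap: %s elements (step %g µm, element %g µm³), %d valid\n",
              paste(dim(x$values), collapse = " x "), x$step,
              x$element_volume, sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  density %.1f-%.1f /1000 µm³ (mean %.1f)\n",
                min(x$values[x$valid]), max(x$values[x$valid]),
                mean(x$values[x$valid])))
  invisible(x)
}

#' Summarize spatial heterogeneity of a density map
#'
#' Mean, s.d., coefficient of variation and range over the valid elements.
#' For a homogeneous random field the element counts are Poisson, so the
#' CV should be near `1/sqrt(mean count)`; a CV well above that Poisson
#' floor quantifies genuine spatial heterogeneity.
#'
#' @param map a `DensityMap`.
#' @return list with `mean`, `sd`, `cv`, `min`, `max`, `n_valid`,
#'   `poisson_cv` (the Poisson-only expectation).
#' @export
heterogeneity_summary <- function(map) {
  stopifnot(inherits(map, "DensityMap"))
  v <- map$values[map$valid]
  if (length(v) == 0) stop("no valid element", call. = FALSE)
  m <- mean(v)
  s <- if (length(v) > 1) stats::sd(v) else 0
  mean_count <- mean(map$counts[map$valid])
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_,
       min = min(v), max = max(v), n_valid = length(v),
       poisson_cv = if (mean_count > 0) 1 / sqrt(mean_count) else NA_real_)
}
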