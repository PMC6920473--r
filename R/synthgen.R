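#' Generate a hard-core random bouton field with known ground truth
#'
#' Samples bouton centers uniformly in a box under a minimum pairwise
#' separation (hard-core point process), emulating non-interpenetrating
#' presynaptic boutons. The number of boutons is a Poisson draw with mean
#' `rho * volume`, then placed by sequential rejection; a retry cap makes
#' infeasible packings an explicit error rather than a silent hang.
#'
#' Default radii give bouton volumes around 3.1 µm³, the middle of the
#' 2.5-4 µm³ range reported for honey-bee calyx microglomeruli.
#'
#' @param region extent `(z, y, x)` of the field in µm, or a 2x3 matrix of
#'   `(lo, hi)` bounds per axis.
#' @param rho target density in boutons/µm³.
#' @param radius_mean,radius_sd mean and s.d. of bouton radius (µm).
#' @param min_sep minimum center-to-center separation (µm); default twice
#'   the mean radius so spheres do not interpenetrate.
#' @param seed optional integer seed (sets R's RNG).
#' @param intensity_mean,intensity_sd per-bouton peak amplitude distribution.
#' @param max_tries rejection-sampling retry cap (total proposals).
#' @return A `BoutonField`: list with `centers` (n x 3, z/y/x µm), `radii`,
#'   `intensities`, `region` (2x3 lo/hi), `rho`, `min_sep`, `seed`.
#' @examples
#' f <- generate_field(c(20, 20, 20), rho = 0.01, seed = 1)
#' nrow(f$centers)
#' @export
generate_field <- function(region, rho, radius_mean = 0.9, radius_sd = 0.1,
                           min_sep = 2 * radius_mean, seed = NULL,
                           intensity_mean = 1, intensity_sd = 0,
                           max_tries = NULL) {
  region <- as_region(region)
  if (!is.null(seed)) set.seed(seed)
  vol <- prod(region[2, ] - region[1, ])
  stopifnot(rho > 0, vol > 0, radius_mean > 0, min_sep >= 0)
  n <- stats::rpois(1, rho * vol)
  if (is.null(max_tries)) max_tries <- max(1000L, 200L * n)
  pts <- .hardcore_sample(n, region[1, ], region[2, ], min_sep,
                          as.integer(max_tries))
  if (isTRUE(attr(pts, "failed")))
    stop("packing infeasible: could not place ", n, " centers with min_sep ",
         min_sep, " µm after ", max_tries, " proposals", call. = FALSE)
  n <- nrow(pts)
  radii <- pmax(stats::rnorm(n, radius_mean, radius_sd), 0.2 * radius_mean)
  intens <- pmax(stats::rnorm(n, intensity_mean, intensity_sd),
                 0.1 * intensity_mean)
  colnames(pts) <- c("z", "y", "x")
  structure(list(centers = pts, radii = radii, intensities = intens,
                 region = region, rho = rho, min_sep = min_sep, seed = seed),
            class = "BoutonField")
}

as_region <- function(region) {
  if (is.matrix(region)) {
    stopifnot(nrow(region) == 2L, ncol(region) == 3L)
    return(region)
  }
  stopifnot(length(region) == 3L, all(region > 0))
  rbind(lo = c(0, 0, 0), hi = as.numeric(region))
}

#' @export
print.BoutonField <- function(x, ...) {
  cat(sprintf("BoutonField: %d boutons in %g x %g x %g µm (rho target %g/µm³)\n",
              nrow(x$centers), x$region[2, 1] - x$region[1, 1],
              x$region[2, 2] - x$region[1, 2], x$region[2, 3] - x$region[1, 3],
              x$rho))
  invisible(x)
}

#' Imaging model for synthetic stack rendering
#'
#' Bundles the physics applied on top of the geometric bouton field:
#' the PSF blur, depth attenuation and its optional compensation, the axial
#' stretch mimicking refractive-index mismatch, and the noise model
#' (Poisson photon statistics plus Gaussian read noise).
#'
#' @param psf a [psf_model()], or `NULL` for an ideal (delta) PSF.
#' @param photon_scale photons per intensity unit (Poisson scale); `Inf`
#'   disables shot noise.
#' @param read_noise_sd Gaussian read-noise s.d. (intensity units).
#' @param attenuation_length scattering attenuation length `d` in µm
#'   (`Inf` = no attenuation): signal decays as `exp(-(z - z0)/d)`.
#' @param compensation optional [compensation_params()]; when supplied, a
#'   depth-dependent gain `P(z)/P(z0)` multiplies the signal, emulating the
#'   exponential laser-power ramp used at acquisition.
#' @param axial_stretch factor `>= 1` elongating rendered boutons along z
#'   (refractive-index distortion of the optical axis).
#' @param clip optional full-scale value at which rendered intensities are
#'   clipped (simulated saturation); `NULL` = no clipping.
#' @return A list of class `RenderSpec`.
#' @export
render_spec <- function(psf = NULL, photon_scale = Inf, read_noise_sd = 0,
                        attenuation_length = Inf, compensation = NULL,
                        axial_stretch = 1, clip = NULL) {
  stopifnot(photon_scale > 0, read_noise_sd >= 0, attenuation_length > 0,
            axial_stretch >= 1)
  structure(list(psf = psf, photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd,
                 attenuation_length = attenuation_length,
                 compensation = compensation, axial_stretch = axial_stretch,
                 clip = clip),
            class = "RenderSpec")
}

#' Render a bouton field into a synthetic image stack
#'
#' Each bouton is rasterized as a solid sphere (axially stretched by
#' `spec$axial_stretch` into a prolate spheroid), the stack is convolved
#' with the PSF, depth attenuation and optional compensation gain are
#' applied slice-wise, and Poisson + Gaussian noise is added. The ground
#' truth table of centers travels with the result as attribute `"truth"`.
#'
#' @param field a `BoutonField` from [generate_field()].
#' @param spec a [render_spec()].
#' @param voxel_size `(dz, dy, dx)` in µm; each axis must sample the
#'   rendered bouton semi-axis (radius, axially times `axial_stretch`)
#'   with at least two voxels.
#' @param seed optional seed for the noise draws.
#' @return A `VoxelGrid`; `attr(, "truth")` is a data.frame of true centers
#'   (z, y, x in µm, radius, intensity).
#' @export
render_stack <- function(field, spec = render_spec(), voxel_size = c(0.5, 0.34, 0.34),
                         seed = NULL) {
  stopifnot(inherits(field, "BoutonField"), inherits(spec, "RenderSpec"))
  if (!is.null(seed)) set.seed(seed)
  semi_mean <- mean(field$radii) * c(spec$axial_stretch, 1, 1)
  if (any(voxel_size > semi_mean / 2 + 1e-9))
    stop("voxel size too coarse: each axis must sample the rendered bouton ",
         "semi-axis with at least two voxels", call. = FALSE)
  if (any(field$intensities < 0)) stop("negative amplitudes", call. = FALSE)
  ext <- field$region[2, ] - field$region[1, ]
  dims <- pmax(2L, as.integer(round(ext / voxel_size)))
  img <- array(0, dims)

  # rasterize stretched solid spheres over local sub-grids
  for (i in seq_len(nrow(field$centers))) {
    ctr <- field$centers[i, ] - field$region[1, ]
    r <- field$radii[i]
    semi <- c(r * spec$axial_stretch, r, r)
    lo <- pmax(1L, as.integer(floor((ctr - semi) / voxel_size)) + 1L)
    hi <- pmin(dims, as.integer(ceiling((ctr + semi) / voxel_size)))
    if (any(lo > hi)) next
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    # voxel centers in µm relative to the bouton center, per axis
    dz2 <- (((zi - 0.5) * voxel_size[1] - ctr[1]) / semi[1])^2
    dy2 <- (((yi - 0.5) * voxel_size[2] - ctr[2]) / semi[2])^2
    dx2 <- (((xi - 0.5) * voxel_size[3] - ctr[3]) / semi[3])^2
    q <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    img[zi, yi, xi] <- img[zi, yi, xi] + field$intensities[i] * (q <= 1)
  }

  if (!is.null(spec$psf))
    img <- convolve_psf(img, spec$psf, voxel_size)

  # depth attenuation and compensation gain, slice-wise; z0 = top of stack
  z_um <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  gain <- rep(1, dims[1])
  if (is.finite(spec$attenuation_length))
    gain <- gain * exp(-(z_um - z_um[1]) / spec$attenuation_length)
  if (!is.null(spec$compensation)) {
    p <- compensate_power(pmin(pmax(z_um, spec$compensation$z0),
                               spec$compensation$zf), spec$compensation)
    gain <- gain * p / spec$compensation$P0
  }
  img <- img * gain  # recycles along z (first dimension)

  if (is.finite(spec$photon_scale))
    img[] <- stats::rpois(length(img), pmax(img, 0) * spec$photon_scale) /
      spec$photon_scale
  if (spec$read_noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$read_noise_sd)
  img <- pmax(img, 0)
  full_scale <- spec$clip
  if (!is.null(spec$clip)) img <- pmin(img, spec$clip)

  out <- voxel_grid(array(img, dims), voxel_size, full_scale = full_scale)
  truth <- data.frame(z = field$centers[, 1] - field$region[1, 1],
                      y = field$centers[, 2] - field$region[1, 2],
                      x = field$centers[, 3] - field$region[1, 3],
                      radius = field$radii, intensity = field$intensities)
  attr(out, "truth") <- truth
  out
}

#' Count boutons per ROI under different boundary conventions
#'
#' Simulates ROI counting directly on the geometric field (no imaging), for
#' three counting rules: `"intersect"` counts a bouton when its sphere
#' intersects the ROI box (the convention of both manual and automated
#' counting, the source of the boundary bias); `"center"` counts it when
#' its center lies in the half-open box (unbiased, expectation `rho * V`);
#' `"majority"` when more than half its volume lies inside (Monte-Carlo
#' volume fraction).
#'
#' @param field a `BoutonField`.
#' @param rois list of [roi_spec()] objects, or a numeric vector of cube
#'   sides in µm (cubes are then centered in the field).
#' @param rule counting rule.
#' @param mc_samples Monte-Carlo samples per bouton for `"majority"`.
#' @return data.frame with `side` (NA for non-cubes), `volume`, `count`.
#' @export
simulate_roi_counts <- function(field, rois, rule = c("intersect", "center", "majority"),
                                mc_samples = 10000L) {
  rule <- match.arg(rule)
  stopifnot(inherits(field, "BoutonField"))
  if (is.numeric(rois)) {
    ctr <- colMeans(field$region)
    rois <- lapply(rois, function(s) roi_spec(ctr - s / 2, s))
  }
  margin <- if (length(field$radii)) max(field$radii) else 0
  for (roi in rois) {
    if (any(roi$origin < field$region[1, ] - 1e-9) ||
        any(roi$origin + roi$size > field$region[2, ] + 1e-9))
      stop("ROI exceeds field region", call. = FALSE)
    if (rule != "center" &&
        (any(roi$origin - margin < field$region[1, ] - 1e-9) ||
         any(roi$origin + roi$size + margin > field$region[2, ] + 1e-9)))
      stop("ROI must keep a margin >= max bouton radius inside the field",
           call. = FALSE)
  }
  counts <- vapply(rois, function(roi) {
    switch(rule,
      center = sum(roi_contains(roi, field$centers)),
      intersect = sum(sphere_box_intersects(field$centers, field$radii, roi)),
      majority = sum(sphere_box_majority(field$centers, field$radii, roi,
                                         mc_samples)))
  }, numeric(1))
  side <- vapply(rois, function(r)
    if (max(r$size) - min(r$size) < 1e-9) r$size[1] else NA_real_, numeric(1))
  data.frame(side = side,
             volume = vapply(rois, function(r) r$volume, numeric(1)),
             count = counts)
}

# exact closest-point test: sphere intersects box iff the distance from the
# center to the box is < r (touching counts as intersecting via <=)
sphere_box_intersects <- function(centers, radii, roi) {
  lo <- roi$origin
  hi <- roi$origin + roi$size
  cl <- pmin(pmax(centers, rep(lo, each = nrow(centers))),
             rep(hi, each = nrow(centers)))
  d2 <- rowSums((centers - cl)^2)
  d2 <= radii^2
}

sphere_box_majority <- function(centers, radii, roi, mc_samples) {
  lo <- roi$origin
  hi <- roi$origin + roi$size
  n <- nrow(centers)
  out <- logical(n)
  for (i in seq_len(n)) {
    # quick outs: sphere entirely inside / outside
    ctr <- centers[i, ]
    r <- radii[i]
    if (all(ctr - r >= lo) && all(ctr + r <= hi)) { out[i] <- TRUE; next }
    cl <- pmin(pmax(ctr, lo), hi)
    if (sum((ctr - cl)^2) > r^2) { out[i] <- FALSE; next }
    # uniform samples in the sphere
    u <- matrix(stats::rnorm(3 * mc_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * r * stats::runif(mc_samples)^(1 / 3)
    p <- sweep(u, 2, ctr, `+`)
    inside <- p[, 1] >= lo[1] & p[, 1] < hi[1] &
      p[, 2] >= lo[2] & p[, 2] < hi[2] &
      p[, 3] >= lo[3] & p[, 3] < hi[3]
    out[i] <- mean(inside) > 0.5
  }
  out
}

#' Expected intersect-inside count for a cubic ROI (Minkowski sum)
#'
#' For spheres of radius `r` at density `rho`, the expected number whose
#' sphere intersects an `L`-sided cube is `rho` times the volume of the cube
#' dilated by `r`: `rho * (L^3 + 6 r L^2 + 3 pi r^2 L + 4/3 pi r^3)`.
#' The leading surface term `6 r rho L^2` is the boundary-effect excess
#' that the surface-scaling count model captures.
#'
#' @param L cube side (µm); @param rho density (/µm³); @param r sphere radius.
#' @return expected count.
#' @export
expected_intersect_count <- function(L, rho, r) {
  rho * (L^3 + 6 * r * L^2 + 3 * pi * r^2 * L + 4 / 3 * pi * r^3)
}
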