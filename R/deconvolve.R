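#' Point spread function model
#'
#' Either a parametric 3D Gaussian (the default route: bead stacks are
#' summarized by Gaussian-fit sigmas) or an explicit measured kernel.
#' Sigmas are physical (µm); a kernel carries its own voxel size and is
#' normalized to unit sum so deconvolution conserves flux.
#'
#' @param sigma `(sigma_z, sigma_y, sigma_x)` in µm (Gaussian route).
#' @param kernel small non-negative 3D array (measured route).
#' @param voxel_size voxel size of `kernel` in µm (required with `kernel`).
#' @return An object of class `PSFModel`.
#' @examples
#' psf_model(sigma = c(1.15, 0.3, 0.3))  # axially elongated two-photon PSF
#' @export
psf_model <- function(sigma = NULL, kernel = NULL, voxel_size = NULL) {
  if (is.null(sigma) == is.null(kernel))
    stop("supply exactly one of 'sigma' or 'kernel'", call. = FALSE)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == 3L, all(sigma > 0))
    return(structure(list(type = "gaussian", sigma = as.numeric(sigma)),
                     class = "PSFModel"))
  }
  stopifnot(is.array(kernel), length(dim(kernel)) == 3L, all(kernel >= 0),
            !is.null(voxel_size))
  s <- sum(kernel)
  if (s <= 0) stop("kernel must have positive sum", call. = FALSE)
  structure(list(type = "kernel", kernel = kernel / s,
                 voxel_size = as.numeric(voxel_size)),
            class = "PSFModel")
}

#' @export
print.PSFModel <- function(x, ...) {
  if (x$type == "gaussian")
    cat(sprintf("PSFModel: Gaussian, sigma (z,y,x) = %.3g / %.3g / %.3g µm\n",
                x$sigma[1], x$sigma[2], x$sigma[3]))
  else
    cat(sprintf("PSFModel: measured kernel %s voxels\n",
                paste(dim(x$kernel), collapse = " x ")))
  invisible(x)
}

# 1D Gaussian tap vector for sigma (um) at spacing (um); unit sum, odd length
gaussian_taps <- function(sigma, spacing, truncate = 4) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(truncate * sigma / spacing))
  x <- (-half:half) * spacing
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array with a PSF at given voxel size, reflective padding
convolve_psf <- function(img, psf, voxel_size) {
  if (psf$type == "gaussian") {
    kernels <- list(gaussian_taps(psf$sigma[1], voxel_size[1]),
                    gaussian_taps(psf$sigma[2], voxel_size[2]),
                    gaussian_taps(psf$sigma[3], voxel_size[3]))
    out <- .conv_sep_reflect(as.numeric(img), dim(img), kernels)
  } else {
    out <- .conv3d_reflect(as.numeric(img), dim(img),
                           as.numeric(psf$kernel), dim(psf$kernel))
  }
  array(out, dim(img))
}

#' Measure the PSF from a fluorescent-bead stack
#'
#' Sub-resolution beads image as isolated replicas of the PSF. Bead
#' candidates are local maxima well above background (greater than
#' background plus `snr_min` background deviations); each is fit with a 3D
#' Gaussian (background + amplitude + center + per-axis sigmas) over a
#' local window, and the per-axis sigmas are averaged across beads.
#'
#' @param bead_stack a `VoxelGrid` of the bead image.
#' @param snr_min minimum peak elevation in background-MAD units.
#' @param window_um half-size of the fit window around each peak (µm).
#' @param max_beads fit at most this many (brightest) beads.
#' @return A Gaussian [psf_model()]; `attr(, "fits")` holds the per-bead
#'   sigma table.
#' @export
measure_psf <- function(bead_stack, snr_min = 10, window_um = 1.5, max_beads = 10L) {
  stopifnot(inherits(bead_stack, "VoxelGrid"))
  img <- bead_stack$data
  vs <- bead_stack$voxel_size
  bg <- stats::median(img)
  noise <- stats::mad(img)
  if (noise == 0) noise <- max(stats::sd(img), .Machine$double.eps)
  thr <- bg + snr_min * noise
  peaks <- local_maxima_3d(img, thr)
  if (nrow(peaks) == 0) stop("no bead found", call. = FALSE)
  ord <- order(-peaks[, 4])
  peaks <- peaks[ord[seq_len(min(nrow(peaks), max_beads))], , drop = FALSE]
  win <- pmax(2L, ceiling(window_um / vs))
  fits <- lapply(seq_len(nrow(peaks)), function(i)
    fit_bead(img, peaks[i, 1:3], win, vs, bg))
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(fits) || nrow(fits) == 0)
    stop("fit non-convergence: no bead could be fit", call. = FALSE)
  sig <- colMeans(fits[, c("sigma_z", "sigma_y", "sigma_x"), drop = FALSE])
  out <- psf_model(sigma = sig)
  attr(out, "fits") <- as.data.frame(fits)
  out
}

# integer-index local maxima above thr with a 1-voxel exclusion shell;
# returns matrix [n x 4] of (z, y, x, value), 1-based indices
local_maxima_3d <- function(img, thr) {
  d <- dim(img)
  cand <- which(img > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    z <- cand[i, 1]; y <- cand[i, 2]; x <- cand[i, 3]
    zi <- max(1, z - 1):min(d[1], z + 1)
    yi <- max(1, y - 1):min(d[2], y + 1)
    xi <- max(1, x - 1):min(d[3], x + 1)
    keep[i] <- img[z, y, x] >= max(img[zi, yi, xi])
  }
  cand <- cand[keep, , drop = FALSE]
  cbind(cand, value = img[cand])
}

# least-squares 3D Gaussian fit around one peak; returns named vector or NULL
fit_bead <- function(img, peak, win, vs, bg) {
  peak <- unname(peak)
  d <- dim(img)
  zi <- max(1, peak[1] - win[1]):min(d[1], peak[1] + win[1])
  yi <- max(1, peak[2] - win[2]):min(d[2], peak[2] + win[2])
  xi <- max(1, peak[3] - win[3]):min(d[3], peak[3] + win[3])
  sub <- img[zi, yi, xi]
  zc <- (zi - 0.5) * vs[1]; yc <- (yi - 0.5) * vs[2]; xc <- (xi - 0.5) * vs[3]
  grid <- expand.grid(z = zc, y = yc, x = xc)
  v <- as.numeric(sub)
  amp0 <- max(v) - bg
  p0 <- c(bg = bg, amp = amp0,
          z0 = (peak[1] - 0.5) * vs[1], y0 = (peak[2] - 0.5) * vs[2],
          x0 = (peak[3] - 0.5) * vs[3],
          lsz = log(vs[1]), lsy = log(vs[2]), lsx = log(vs[3]))
  model <- function(p) {
    p["bg"] + p["amp"] * exp(
      -((grid$z - p["z0"])^2 / (2 * exp(2 * p["lsz"])) +
        (grid$y - p["y0"])^2 / (2 * exp(2 * p["lsy"])) +
        (grid$x - p["x0"])^2 / (2 * exp(2 * p["lsx"]))))
  }
  fit <- try(stats::optim(p0, function(p) sum((model(p) - v)^2),
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) return(NULL)
  p <- fit$par
  c(sigma_z = exp(unname(p["lsz"])), sigma_y = exp(unname(p["lsy"])),
    sigma_x = exp(unname(p["lsx"])), amp = unname(p["amp"]))
}

#' Richardson-Lucy maximum-likelihood deconvolution
#'
#' Iterative restoration under the Poisson imaging model:
#' `x <- x * C(y / C(x))` with `C` the PSF convolution. The convolution
#' uses half-sample symmetric (reflective) padding, under which a symmetric
#' kernel gives a self-adjoint operator that maps constants to constants —
#' so each update is an exact EM step and the Poisson negative
#' log-likelihood is non-increasing across iterations.
#'
#' @param grid a non-negative `VoxelGrid`.
#' @param psf a [psf_model()].
#' @param iterations fixed iteration count (default 100, sufficient for
#'   convergence in this class of stacks).
#' @param stop_tol optional early-stop tolerance on the relative L1 change
#'   of the estimate between iterations.
#' @param track_nll if `TRUE`, record the Poisson negative log-likelihood
#'   per iteration in `attr(, "nll")`.
#' @return The deconvolved `VoxelGrid` (same shape, non-negative).
#' @export
richardson_lucy <- function(grid, psf, iterations = 100L, stop_tol = NULL,
                            track_nll = FALSE) {
  stopifnot(inherits(grid, "VoxelGrid"), inherits(psf, "PSFModel"))
  y <- grid$data
  if (any(!is.finite(y))) stop("non-finite values in input", call. = FALSE)
  if (any(y < 0)) stop("input must be non-negative", call. = FALSE)
  vs <- grid$voxel_size
  x <- y
  eps <- .Machine$double.eps
  nll <- if (track_nll) numeric(iterations) else NULL
  for (it in seq_len(iterations)) {
    blur <- convolve_psf(x, psf, vs)
    if (track_nll) nll[it] <- sum(blur - y * log(pmax(blur, eps)))
    ratio <- y / pmax(blur, eps)
    x_new <- x * convolve_psf(ratio, psf, vs)
    if (!is.null(stop_tol)) {
      rel <- sum(abs(x_new - x)) / max(sum(abs(x)), eps)
      x <- x_new
      if (rel < stop_tol) break
    } else x <- x_new
  }
  out <- voxel_grid(pmax(x, 0), vs, full_scale = grid$full_scale)
  if (track_nll) attr(out, "nll") <- nll[seq_len(it)]
  out
}

#' Resample a stack to isotropic voxels
#'
#' Trilinear interpolation onto an isotropic grid (default 0.1 µm), the
#' working resolution of the segmentation stage. The physical extent is
#' preserved to within one output voxel.
#'
#' @param grid a `VoxelGrid`.
#' @param target isotropic voxel size in µm.
#' @return A `VoxelGrid` at `(target, target, target)` µm.
#' @export
resample_isotropic <- function(grid, target = 0.1) {
  stopifnot(inherits(grid, "VoxelGrid"), target > 0)
  if (target > 2 * min(grid$voxel_size))
    warning("target spacing coarser than twice the finest input spacing; ",
            "information will be lost", call. = FALSE)
  vs <- grid$voxel_size
  if (all(abs(vs - target) < 1e-12)) return(grid)
  out <- .trilinear_resample(as.numeric(grid$data), dim(grid$data),
                             vs, rep(target, 3))
  voxel_grid(array(out, attr(out, "dim")), rep(target, 3),
             full_scale = grid$full_scale)
}

#' Crop slices from both z ends of a stack
#'
#' Deconvolution ringing concentrates at the axial boundaries; cropping a
#' fixed physical margin (default 5 µm) from each end removes it, e.g.
#' turning a 50 µm acquisition into a 40 µm working subregion.
#'
#' @param grid a `VoxelGrid`.
#' @param margin physical margin in µm removed from each z end.
#' @return The cropped `VoxelGrid`.
#' @export
crop_z <- function(grid, margin = 5) {
  stopifnot(inherits(grid, "VoxelGrid"), margin >= 0)
  if (margin == 0) return(grid)
  dz <- grid$voxel_size[1]
  n <- dim(grid$data)[1]
  k <- round(margin / dz)
  if (n - 2 * k < 1)
    stop("stack thinner than twice the crop margin", call. = FALSE)
  voxel_grid(grid$data[(k + 1):(n - k), , , drop = FALSE], grid$voxel_size,
             full_scale = grid$full_scale)
}
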