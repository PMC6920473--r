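#' 3D image stack with physical voxel size
#'
#' The universal image container of the package: a numeric 3D array of
#' non-negative intensities together with its voxel size in micrometres.
#' The axis convention is fixed to `(z, y, x)` with `z` (array dimension 1)
#' the optical axis; all physical coordinates in the package are in µm.
#'
#' @param data numeric 3D array, non-negative intensities (arbitrary units).
#' @param voxel_size numeric length-3, voxel edge lengths `(dz, dy, dx)` in µm.
#' @param full_scale optional numeric, the detector full-scale value (e.g. 255
#'   for 8-bit data); used by [check_saturation()] for floating-point stacks.
#' @return An object of class `VoxelGrid`: a list with elements `data`,
#'   `voxel_size` and optionally `full_scale`.
#' @examples
#' g <- voxel_grid(array(runif(8 * 8 * 8), c(8, 8, 8)), c(0.5, 0.34, 0.34))
#' grid_extent(g)
#' @export
voxel_grid <- function(data, voxel_size, full_scale = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D data: 'data' must be a 3D array", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive values (dz, dy, dx) in µm",
         call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 full_scale = full_scale),
            class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VoxelGrid: %d x %d x %d voxels (z,y,x), voxel %g x %g x %g µm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  extent %.2f x %.2f x %.2f µm, intensity range [%g, %g]\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2], d[3] * x$voxel_size[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.VoxelGrid <- function(x) dim(x$data)

#' @rdname voxel_grid
#' @param grid a `VoxelGrid`.
#' @return `grid_extent()`: the physical extent `(z, y, x)` of the stack in µm.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "VoxelGrid"))
  dim(grid$data) * grid$voxel_size
}

#' @rdname voxel_grid
#' @return `voxel_volume()`: the volume of one voxel in µm³.
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

#' Cubic or box-shaped region of interest
#'
#' A ROI is an axis-aligned box in physical coordinates, interpreted as the
#' half-open interval `[origin, origin + size)` on each axis so that adjacent
#' ROIs sharing a face never double-count a center lying on it.
#'
#' @param origin numeric length-3, `(z, y, x)` corner in µm.
#' @param size numeric length-3, box edge lengths `(dz, dy, dx)` in µm; a
#'   single value is recycled to a cube.
#' @return An object of class `ROISpec` with fields `origin`, `size` and the
#'   derived `volume` (µm³).
#' @examples
#' roi_spec(c(0, 0, 0), 10)  # the classic 10 x 10 x 10 um counting cube
#' @export
roi_spec <- function(origin, size) {
  if (length(size) == 1L) size <- rep(size, 3L)
  if (length(origin) != 3L || length(size) != 3L)
    stop("'origin' and 'size' must have length 3 (z, y, x)", call. = FALSE)
  if (any(size <= 0)) stop("ROI sizes must be positive", call. = FALSE)
  structure(list(origin = as.numeric(origin), size = as.numeric(size),
                 volume = prod(size)),
            class = "ROISpec")
}

#' @export
print.ROISpec <- function(x, ...) {
  cat(sprintf("ROISpec: origin (%g, %g, %g) µm, size %g x %g x %g µm, V = %g µm³\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$size[1], x$size[2], x$size[3], x$volume))
  invisible(x)
}

# TRUE for points (n x 3, z/y/x um) inside the half-open ROI box.
roi_contains <- function(roi, pts) {
  pts <- matrix(pts, ncol = 3L)
  lo <- roi$origin
  hi <- roi$origin + roi$size
  pts[, 1] >= lo[1] & pts[, 1] < hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] < hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] < hi[3]
}

stopifnot_roi_inside <- function(roi, grid) {
  ext <- grid_extent(grid)
  if (any(roi$origin < 0) || any(roi$origin + roi$size > ext + 1e-9))
    stop("ROI extends outside the image stack", call. = FALSE)
  invisible(TRUE)
}
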